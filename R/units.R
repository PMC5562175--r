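#' Convert serum creatinine between micromol/L and mg/dL
#'
#' UK laboratories report serum creatinine in micromol/L, most US-derived
#' equations expect mg/dL. The definitional molar conversion factor is
#' 88.42 micromol/L per mg/dL.
#'
#' @param value Numeric vector of creatinine concentrations.
#' @param from,to Unit strings, one of `"umol/L"` or `"mg/dL"`
#'   (the spelled-out `"µmol/L"` is accepted as an alias).
#' @return Numeric vector in the `to` unit.
#' @export
#' @examples
#' convert_creatinine(1.0, "mg/dL", "umol/L")  # 88.42
convert_creatinine <- function(value, from, to) {
  from <- normalize_unit(from)
  to <- normalize_unit(to)
  if (length(from) == 1 && length(to) == 1 && from == to) return(value)
  value * ifelse(from == "mg/dL", 88.42, 1) / ifelse(to == "mg/dL", 88.42, 1)
}

CREATININE_UNITS <- c("umol/L", "mg/dL")

normalize_unit <- function(unit) {
  unit <- trimws(as.character(unit))
  unit[unit %in% c("µmol/L", "umol/l", "micromol/L")] <- "umol/L"
  unit[tolower(unit) == "mg/dl"] <- "mg/dL"
  bad <- !(unit %in% CREATININE_UNITS)
  if (any(bad)) {
    stop("unknown creatinine unit: ", paste(unique(unit[bad]), collapse = ", "),
         " (expected 'umol/L' or 'mg/dL')", call. = FALSE)
  }
  unit
}

#' Du Bois body surface area
#'
#' BSA (m^2) = 0.007184 * height^0.725 * weight^0.425, with height in cm
#' and weight in kg.
#'
#' @param height_cm Height in centimetres, > 0.
#' @param weight_kg Weight in kilograms, > 0.
#' @return Body surface area in square metres.
#' @export
#' @examples
#' du_bois_bsa(170, 70)  # about 1.810
du_bois_bsa <- function(height_cm, weight_kg) {
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be finite and positive", call. = FALSE)
  }
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream so seeded helpers stay pure.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
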