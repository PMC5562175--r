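#' Published creatinine-based GFR estimation equations
#'
#' @description
#' Seven published equations behind one registry interface. Coefficients
#' were transcribed from the primary references and are tabulated here as
#' the package's constants record:
#'
#' | id | reference form | creatinine unit | native scale |
#' |----|----------------|-----------------|--------------|
#' | `cockcroft_gault` | Cockcroft & Gault 1976: (140-Age) x Wt / (72 x SCr), x0.85 female | mg/dL | mL/min |
#' | `jelliffe` | Jelliffe 1973 variant: (98 - 0.8 x (Age-20)) / SCr, x0.9 female | mg/dL | mL/min/1.73m2 |
#' | `wright` | Wright 2001: (6580 - 38.8 x Age) x BSA x (1 - 0.168 x female) / SCr | micromol/L | mL/min |
#' | `martin` | Martin 1998: 163 x Wt x (1 - 0.00496 x Age) x (1 - 0.252 x female) / SCr | micromol/L | mL/min |
#' | `mayo` | Mayo quadratic 2004: exp(1.911 + 5.249/SCr - 2.114/SCr^2 - 0.00686 x Age - 0.205 x female), SCr floored at 0.8 | mg/dL | mL/min/1.73m2 |
#' | `mdrd` | IDMS-traceable 4-variable MDRD: 175 x SCr^-1.154 x Age^-0.203 x 0.742 female x 1.212 black | mg/dL | mL/min/1.73m2 |
#' | `ckd_epi` | CKD-EPI 2009: 141 x min(SCr/k,1)^a x max(SCr/k,1)^-1.209 x 0.993^Age x 1.018 female x 1.159 black; k = 0.7 F / 0.9 M, a = -0.329 F / -0.411 M | mg/dL | mL/min/1.73m2 |
#'
#' Race factors (MDRD, CKD-EPI) default to the non-black coefficient and
#' are exposed via the `black` argument. Normalised models (per 1.73 m2)
#' can be converted to absolute mL/min with [bsa_adjust]; the four
#' normalised models are exactly the ones that admit BSA adjustment.
#'
#' @name comparator_models
NULL

#' Registry of comparator equations
#'
#' One row per model: identifier, native output scale and required
#' record fields.
#'
#' @return Data frame with columns `model_id`, `output_scale`
#'   (`"absolute"` or `"normalized"`), `creatinine_unit`, `requires`.
#' @export
comparator_specs <- function() {
  data.frame(
    model_id = c("cockcroft_gault", "jelliffe", "wright", "martin",
                 "mayo", "mdrd", "ckd_epi"),
    output_scale = c("absolute", "normalized", "absolute", "absolute",
                     "normalized", "normalized", "normalized"),
    creatinine_unit = c("mg/dL", "mg/dL", "umol/L", "umol/L",
                        "mg/dL", "mg/dL", "mg/dL"),
    requires = c("age,sex,weight_kg,creatinine",
                 "age,sex,creatinine",
                 "age,sex,height_cm,weight_kg,creatinine",
                 "age,sex,weight_kg,creatinine",
                 "age,sex,creatinine",
                 "age,sex,creatinine",
                 "age,sex,creatinine"),
    stringsAsFactors = FALSE
  )
}

check_inputs <- function(model_id, cohort, fields) {
  for (fld in fields) {
    if (is.null(cohort[[fld]]) || any(is.na(cohort[[fld]]))) {
      stop(model_id, ": missing required input '", fld, "'", call. = FALSE)
    }
  }
}

#' Evaluate one comparator equation on a cohort
#'
#' Returns the estimate on the model's native scale (absolute mL/min for
#' Cockcroft-Gault, Wright and Martin; mL/min/1.73 m2 for Jelliffe,
#' Mayo, MDRD and CKD-EPI). Creatinine is converted centrally to the
#' unit each formula expects.
#'
#' @param model_id One of the identifiers in [comparator_specs].
#' @param cohort A [gfr_cohort] (or one-row record).
#' @param black Logical; apply the published black-race factor in MDRD /
#'   CKD-EPI (default `FALSE`).
#' @return Numeric vector of estimates on the native scale.
#' @export
estimate_comparator <- function(model_id, cohort, black = FALSE) {
  spec <- comparator_specs()
  row <- spec[spec$model_id == model_id, ]
  if (nrow(row) != 1) stop("unknown comparator model: ", model_id,
                           call. = FALSE)
  check_inputs(model_id, cohort, strsplit(row$requires, ",")[[1]])
  scr <- creatinine_in(cohort, row$creatinine_unit)
  female <- cohort$sex == "F"
  age <- cohort$age
  out <- switch(model_id,
    cockcroft_gault = (140 - age) * cohort$weight_kg / (72 * scr) *
      ifelse(female, 0.85, 1),
    jelliffe = (98 - 0.8 * (age - 20)) / scr * ifelse(female, 0.9, 1),
    wright = (6580 - 38.8 * age) *
      du_bois_bsa(cohort$height_cm, cohort$weight_kg) *
      (1 - 0.168 * female) / scr,
    martin = 163 * cohort$weight_kg * (1 - 0.00496 * age) *
      (1 - 0.252 * female) / scr,
    mayo = {
      s <- pmax(scr, 0.8)  # published low-creatinine floor
      exp(1.911 + 5.249 / s - 2.114 / s^2 - 0.00686 * age -
            0.205 * female)
    },
    mdrd = 175 * scr^-1.154 * age^-0.203 *
      ifelse(female, 0.742, 1) * ifelse(black, 1.212, 1),
    ckd_epi = {
      kappa <- ifelse(female, 0.7, 0.9)
      alpha <- ifelse(female, -0.329, -0.411)
      141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^-1.209 *
        0.993^age * ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
    })
  out
}

# Models whose normalised output the evaluation pipeline BSA-adjusts.
BSA_ADJUSTABLE <- c("jelliffe", "mayo", "mdrd", "ckd_epi")

#' Convert a normalised eGFR to absolute mL/min
#'
#' Multiplies a per-1.73 m2 estimate by `bsa / 1.73`. Applying it to a
#' model whose native scale is already absolute is a scale error; pass
#' `model_id` to enforce this.
#'
#' @param value eGFR in mL/min/1.73 m2.
#' @param bsa Body surface area in m2.
#' @param model_id Optional identifier checked against the registry's
#'   native scale.
#' @return Absolute eGFR in mL/min.
#' @export
bsa_adjust <- function(value, bsa, model_id = NULL) {
  stopifnot(all(value > 0), all(bsa > 0))
  if (!is.null(model_id)) {
    spec <- comparator_specs()
    sc <- spec$output_scale[spec$model_id == model_id]
    if (length(sc) == 1 && sc == "absolute") {
      stop(model_id, " is already on the absolute mL/min scale; ",
           "BSA adjustment does not apply", call. = FALSE)
    }
  }
  value * bsa / 1.73
}

#' Evaluate every comparator on a cohort
#'
#' The seven native models plus, when `include_bsa_adjusted`, the four
#' BSA-adjusted variants of the normalised models (labels suffixed
#' `_bsa_adj`). Per-model input failures do not abort the others: failed
#' models yield `NA` and the messages are attached as the `"errors"`
#' attribute keyed by label.
#'
#' @param cohort A [gfr_cohort] (a one-row cohort gives the per-record
#'   label-to-value map).
#' @param include_bsa_adjusted Include the BSA-adjusted variants.
#' @param black Race-factor flag forwarded to [estimate_comparator].
#' @return Data frame, one column per model label, one row per record.
#' @export
estimate_all <- function(cohort, include_bsa_adjusted = TRUE,
                         black = FALSE) {
  labels <- comparator_specs()$model_id
  out <- list()
  errors <- character(0)
  for (m in labels) {
    val <- tryCatch(estimate_comparator(m, cohort, black = black),
                    error = function(e) {
                      errors[[m]] <<- conditionMessage(e)
                      rep(NA_real_, nrow(cohort))
                    })
    out[[m]] <- val
  }
  if (include_bsa_adjusted) {
    bsa <- tryCatch(du_bois_bsa(cohort$height_cm, cohort$weight_kg),
                    error = function(e) rep(NA_real_, nrow(cohort)))
    for (m in BSA_ADJUSTABLE) {
      lab <- paste0(m, "_bsa_adj")
      out[[lab]] <- if (all(is.na(out[[m]])) || all(is.na(bsa))) {
        if (!m %in% names(errors)) {
          errors[[lab]] <- "BSA or base model unavailable"
        }
        rep(NA_real_, nrow(cohort))
      } else out[[m]] * bsa / 1.73
    }
  }
  res <- as.data.frame(out)
  attr(res, "errors") <- errors
  res
}
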