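#' Patient cohorts
#'
#' A cohort is a data frame with one row per patient and a fixed schema:
#' `patient_id`, `age` (years), `sex` (`"M"`/`"F"`), `height_cm`,
#' `weight_kg`, `creatinine` (in the cohort's single unit), and the
#' optional `measured_gfr` (mL/min, e.g. from 51Cr-EDTA clearance) and
#' `days_between` (days between the creatinine and GFR measurements).
#' The creatinine unit and a free-text label are carried as attributes;
#' the canonical internal unit is micromol/L so downstream equations
#' convert from a single well-defined point.
#'
#' @param records Data frame with the schema above.
#' @param label Free-text provenance label.
#' @param creatinine_unit Unit of the `creatinine` column.
#' @return An object of class `gfr_cohort` (a data frame).
#' @export
gfr_cohort <- function(records, label = "",
                       creatinine_unit = "umol/L") {
  required <- c("patient_id", "age", "sex", "height_cm", "weight_kg",
                "creatinine")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"measured_gfr" %in% names(records)) records$measured_gfr <- NA_real_
  if (!"days_between" %in% names(records)) records$days_between <- NA_real_
  records$sex <- toupper(as.character(records$sex))
  for (col in c("age", "height_cm", "weight_kg", "creatinine",
                "measured_gfr", "days_between")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  rownames(records) <- NULL
  structure(records,
            label = label,
            creatinine_unit = normalize_unit(creatinine_unit),
            class = c("gfr_cohort", "data.frame"))
}

#' @export
print.gfr_cohort <- function(x, ...) {
  cat(sprintf("<gfr_cohort> %d patients, creatinine in %s%s\n",
              nrow(x), attr(x, "creatinine_unit"),
              if (nzchar(attr(x, "label"))) paste0(" [", attr(x, "label"), "]")
              else ""))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

cohort_unit <- function(cohort) attr(cohort, "creatinine_unit")

# Creatinine column of a cohort expressed in `unit`.
creatinine_in <- function(cohort, unit) {
  convert_creatinine(cohort$creatinine, cohort_unit(cohort), unit)
}

#' Validate a single patient record
#'
#' Checks the admission rules: age >= 18, positive height, weight and
#' creatinine, positive measured GFR when present, and a creatinine
#' measurement within 30 days of the GFR measurement when the interval is
#' recorded. Validation never raises; it returns a character vector of
#' violations, empty when the record is admissible.
#'
#' @param record A one-row data frame or named list with the cohort schema.
#' @return Character vector of violation descriptions (possibly empty).
#' @export
validate_record <- function(record) {
  v <- character(0)
  num <- function(x) suppressWarnings(as.numeric(x))
  age <- num(record$age)
  if (!is.finite(age)) v <- c(v, "age: missing or non-numeric")
  else if (age < 18) v <- c(v, "age: below the adult inclusion threshold of 18 years")
  if (!is.null(record$sex) &&
      !toupper(as.character(record$sex)) %in% c("M", "F")) {
    v <- c(v, "sex: must be 'M' or 'F'")
  }
  for (fld in c("height_cm", "weight_kg", "creatinine")) {
    x <- num(record[[fld]])
    if (!is.finite(x) || x <= 0) v <- c(v, paste0(fld, ": must be positive"))
  }
  mg <- num(record$measured_gfr)
  if (length(mg) == 1 && !is.na(mg) && mg <= 0) {
    v <- c(v, "measured_gfr: must be positive when present")
  }
  db <- num(record$days_between)
  if (length(db) == 1 && !is.na(db) && db > 30) {
    v <- c(v, "days_between: creatinine must be measured within 30 days of GFR")
  }
  v
}

# All violations across a cohort: data frame (row, violation), zero rows
# when every record is admissible.
cohort_violations <- function(cohort) {
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    v <- validate_record(cohort[i, , drop = FALSE])
    if (length(v) == 0) NULL else data.frame(row = i, violation = v)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(row = integer(0), violation = character(0))
  else out
}

COHORT_COLUMNS <- c("patient_id", "age", "sex", "height_cm", "weight_kg",
                    "creatinine", "creatinine_unit", "measured_gfr",
                    "days_between")

#' Read a patient cohort from CSV
#'
#' Expects the columns `patient_id,age,sex,height_cm,weight_kg,creatinine`
#' with optional `creatinine_unit`, `measured_gfr` and `days_between`;
#' comma-separated, UTF-8, header required, missing values as empty
#' strings, sex coded M/F case-insensitively. Rows violating the record
#' invariants are not silently dropped: they are removed from the cohort
#' and attached, with reasons, as the `"rejected"` attribute.
#'
#' @param path CSV file path.
#' @param unit Unit to express creatinine in internally (per-row
#'   `creatinine_unit` entries, if present, are converted to it).
#' @param label Cohort label; defaults to the file name.
#' @return A [gfr_cohort] whose records preserve file order, with a
#'   `"rejected"` attribute describing any inadmissible rows.
#' @export
read_cohort <- function(path, unit = "umol/L", label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  unit <- normalize_unit(unit)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  required <- c("patient_id", "age", "sex", "height_cm", "weight_kg",
                "creatinine")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("measured_gfr", "days_between")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  numeric_cols <- c("age", "height_cm", "weight_kg", "creatinine",
                    "measured_gfr", "days_between")
  parsed <- raw
  parse_bad <- character(nrow(raw))
  for (col in numeric_cols) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.na(raw[[col]]) & is.na(val)
    parse_bad[bad] <- paste0(parse_bad[bad], col, ": not numeric; ")
    parsed[[col]] <- val
  }
  if ("creatinine_unit" %in% names(parsed)) {
    row_unit <- normalize_unit(ifelse(is.na(parsed$creatinine_unit),
                                      unit, parsed$creatinine_unit))
    parsed$creatinine <- convert_creatinine(parsed$creatinine, row_unit, unit)
    # unit now uniform; drop per-row column
    parsed$creatinine_unit <- NULL
  }
  cohort <- gfr_cohort(parsed[names(parsed) != "creatinine_unit"],
                       label = label, creatinine_unit = unit)
  reasons <- parse_bad
  for (i in seq_len(nrow(cohort))) {
    if (nzchar(reasons[i])) next
    v <- validate_record(cohort[i, , drop = FALSE])
    if (length(v) > 0) reasons[i] <- paste(v, collapse = "; ")
  }
  keep <- !nzchar(reasons)
  rejected <- data.frame(row = which(!keep),
                         patient_id = raw$patient_id[!keep],
                         reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  out <- gfr_cohort(as.data.frame(cohort)[keep, , drop = FALSE],
                    label = label, creatinine_unit = unit)
  attr(out, "rejected") <- rejected
  out
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort]: emits the standard schema including a
#' `creatinine_unit` column so the file is self-describing.
#'
#' @param cohort A [gfr_cohort].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$creatinine_unit <- cohort_unit(cohort)
  df <- df[, COHORT_COLUMNS]
  # full round-trip precision so read_cohort(write_cohort(x)) == x exactly
  for (col in c("age", "height_cm", "weight_kg", "creatinine",
                "measured_gfr", "days_between")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        sprintf("%.17g", df[[col]]))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Randomly split a cohort into development and validation parts
#'
#' Simple random assignment without stratification. The development size
#' is `round half away from zero` of `ratio * n`, so a 2,471-patient
#' cohort at ratio 0.8 yields 1,977 development and 494 validation
#' records. Identical seeds give identical splits.
#'
#' @param cohort A [gfr_cohort] with at least 2 records.
#' @param ratio Development fraction, strictly between 0 and 1.
#' @param seed Integer seed controlling the assignment.
#' @return List with elements `development` and `validation`, both
#'   [gfr_cohort]s preserving the original record order within each part.
#' @export
split_cohort <- function(cohort, ratio = 0.8, seed = 1L) {
  n <- nrow(cohort)
  if (n < 2) stop("cannot split a cohort with fewer than 2 records",
                  call. = FALSE)
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be in (0, 1)", call. = FALSE)
  n_dev <- floor(ratio * n + 0.5)  # round half away from zero for ratio*n > 0
  n_dev <- min(max(n_dev, 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n, n_dev))
  dev <- sort(idx)
  val <- setdiff(seq_len(n), dev)
  subcohort <- function(rows, tag) {
    out <- gfr_cohort(as.data.frame(cohort)[rows, , drop = FALSE],
                      label = paste0(attr(cohort, "label"), tag),
                      creatinine_unit = cohort_unit(cohort))
    out
  }
  list(development = subcohort(dev, " [development]"),
       validation = subcohort(val, " [validation]"))
}
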