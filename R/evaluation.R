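#' Agreement statistics and dosing analysis
#'
#' @description
#' The comparison framework for measured vs estimated GFR: RMSE with a
#' chi-square confidence interval, median residual / percentage error /
#' absolute percentage error with IQRs, Bland-Altman limits of
#' agreement, carboplatin dose errors via the Calvert equation, the
#' 2x2 classification against a clinical GFR cutoff, predictive-interval
#' coverage, and the multi-model comparison table.
#'
#' Sign conventions, stated once and used throughout: the residual is
#' `measured - estimated` (positive = underestimation); the percentage
#' error is `100 * (estimated - measured) / measured` (negative median
#' PE = overestimation). Bland-Altman differences follow the residual
#' convention.
#'
#' @name evaluation
NULL

#' RMSE with a chi-square confidence interval
#'
#' `rmse = sqrt(sum(r^2) / n)`; treating `n * rmse^2 / sigma^2` as
#' chi-square with `n` degrees of freedom gives the pivot interval
#' `sqrt(n * rmse^2 / q)` with `q` the upper / lower chi-square
#' quantiles at `(1 +- level) / 2`.
#'
#' @param residuals Numeric vector of residuals (mL/min), length >= 2.
#' @param level Confidence level, default 0.95.
#' @return Named vector `c(rmse, lwr, upr)`.
#' @export
rmse_with_ci <- function(residuals, level = 0.95) {
  n <- length(residuals)
  if (n < 2) stop("need at least 2 residuals", call. = FALSE)
  rmse <- sqrt(sum(residuals^2) / n)
  q_hi <- stats::qchisq((1 + level) / 2, df = n)
  q_lo <- stats::qchisq((1 - level) / 2, df = n)
  c(rmse = rmse,
    lwr = sqrt(n * rmse^2 / q_hi),
    upr = sqrt(n * rmse^2 / q_lo))
}

#' Median residual, percentage error and absolute percentage error
#'
#' All medians come with IQRs. Residual = measured - estimated;
#' PE = 100 * (estimated - measured) / measured; APE = |PE|.
#'
#' @param measured,estimated Paired positive GFR values (mL/min).
#' @return One-row data frame with the three medians and their quartile
#'   bounds.
#' @export
summarize_residuals <- function(measured, estimated) {
  if (length(measured) != length(estimated)) {
    stop("measured and estimated must have equal length", call. = FALSE)
  }
  resid <- measured - estimated
  pe <- 100 * (estimated - measured) / measured
  ape <- abs(pe)
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE,
                                    type = 7)
  r <- qs(resid); p <- qs(pe); a <- qs(ape)
  data.frame(median_residual = r[2], residual_q1 = r[1], residual_q3 = r[3],
             median_pe = p[2], pe_q1 = p[1], pe_q3 = p[3],
             median_ape = a[2], ape_q1 = a[1], ape_q3 = a[3])
}

#' Carboplatin dose by the Calvert equation
#'
#' dose (mg) = target AUC (mg/mL/min) x (GFR (mL/min) + 25).
#'
#' @param gfr GFR in mL/min (>= 0).
#' @param target_auc Target AUC, typically 5 (AUC5).
#' @return Dose in mg.
#' @export
calvert_dose <- function(gfr, target_auc = 5) {
  stopifnot(all(gfr >= 0), all(target_auc >= 0))
  target_auc * (gfr + 25)
}

#' Fraction of patients with carboplatin dose APE above a threshold
#'
#' Doses are computed from measured and estimated GFR via the Calvert
#' equation; because of the +25 offset the dose APE differs from the
#' GFR APE (set `on_gfr = TRUE` for the latter as a sensitivity check).
#' The comparison is strict: boundary-equal cases do not exceed.
#'
#' @inheritParams summarize_residuals
#' @param target_auc Calvert target AUC (cancels in the APE but kept for
#'   the interface).
#' @param threshold APE threshold in percent (default 20).
#' @param on_gfr Compute the APE on GFR instead of dose.
#' @return Percentage of patients (0-100) with APE strictly above the
#'   threshold.
#' @export
dose_error_fraction <- function(measured, estimated, target_auc = 5,
                                threshold = 20, on_gfr = FALSE) {
  if (length(measured) != length(estimated)) {
    stop("measured and estimated must have equal length", call. = FALSE)
  }
  stopifnot(threshold > 0)
  if (on_gfr) {
    ape <- 100 * abs(estimated - measured) / measured
  } else {
    ref <- calvert_dose(measured, target_auc)
    est <- calvert_dose(pmax(estimated, 0), target_auc)
    ape <- 100 * abs(est - ref) / ref
  }
  100 * sum(ape > threshold) / length(ape)
}

#' Bland-Altman limits of agreement
#'
#' Differences follow the residual convention (measured - estimated);
#' limits are the mean difference +- 1.96 standard deviations. The
#' returned `points` give the plot coordinates (pairwise means vs
#' differences).
#'
#' @inheritParams summarize_residuals
#' @return List: `mean_difference`, `lower_limit`, `upper_limit`,
#'   `points` (data frame `mean`, `difference`).
#' @export
bland_altman_stats <- function(measured, estimated) {
  if (length(measured) != length(estimated)) {
    stop("measured and estimated must have equal length", call. = FALSE)
  }
  if (length(measured) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- measured - estimated
  m <- (measured + estimated) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  list(mean_difference = md,
       lower_limit = md - 1.96 * sdd,
       upper_limit = md + 1.96 * sdd,
       points = data.frame(mean = m, difference = d))
}

#' 2x2 classification against a clinical GFR cutoff
#'
#' Cross-tabulates `measured < cutoff` against `estimated < cutoff`
#' (strict inequalities on both axes), e.g. at 50 mL/min where full-dose
#' cisplatin warrants caution.
#'
#' @inheritParams summarize_residuals
#' @param cutoff GFR threshold in mL/min (> 0).
#' @return 2x2 integer matrix, rows = measured (`<cutoff`, `>=cutoff`),
#'   columns = estimated likewise.
#' @export
threshold_classification <- function(measured, estimated, cutoff = 50) {
  stopifnot(cutoff > 0, length(measured) == length(estimated))
  m_below <- factor(measured < cutoff, levels = c(TRUE, FALSE))
  e_below <- factor(estimated < cutoff, levels = c(TRUE, FALSE))
  out <- table(measured = m_below, estimated = e_below)
  dimnames(out) <- list(measured = c("<cutoff", ">=cutoff"),
                        estimated = c("<cutoff", ">=cutoff"))
  out
}

#' Predictive-interval coverage on a cohort
#'
#' Fraction of measured GFR values inside their per-patient predictive
#' interval at the given level, and the fraction of intervals that
#' contain a clinical cutoff (the "flagged for caution" rate).
#'
#' @param model A fitted `sqrt_gfr_fit`.
#' @param cohort A [gfr_cohort] with `measured_gfr`.
#' @param level Interval level, default 0.95.
#' @param cutoff Cutoff for the containment fraction, default 50 mL/min.
#' @return List: `coverage`, `cutoff_containment`, `n`, plus the
#'   `intervals` data frame.
#' @export
pi_coverage <- function(model, cohort, level = 0.95, cutoff = 50) {
  ints <- predict_gfr_interval(model, cohort, level = level)
  inside <- cohort$measured_gfr >= ints$lwr & cohort$measured_gfr <= ints$upr
  contains <- ints$lwr < cutoff & cutoff < ints$upr
  list(coverage = mean(inside),
       cutoff_containment = mean(contains),
       n = nrow(cohort),
       intervals = ints)
}

#' Compare a registry of GFR models on one cohort
#'
#' Evaluates every entry of the registry (a named list of functions
#' mapping a cohort to estimated GFR in mL/min) and returns one row per
#' model with RMSE + CI, the median residual / PE / APE with IQRs, and
#' the carboplatin dose APE > threshold fraction, ordered by ascending
#' RMSE. Per-model failures populate the row with `NA` instead of
#' aborting the comparison.
#'
#' @param cohort A [gfr_cohort] with `measured_gfr`.
#' @param registry Named list of estimator functions
#'   (`function(cohort) -> mL/min vector`); see [default_registry].
#' @param target_auc,threshold Dose-error settings (AUC5, 20%).
#' @param level RMSE confidence level.
#' @return Data frame of class `evaluation_report`.
#' @export
compare_models <- function(cohort, registry, target_auc = 5,
                           threshold = 20, level = 0.95) {
  stopifnot(length(registry) > 0, !is.null(names(registry)))
  # percentage errors are undefined at measured GFR 0; restrict the
  # comparison to records with a positive reference measurement
  usable <- !is.na(cohort$measured_gfr) & cohort$measured_gfr > 0
  if (!all(usable)) {
    message(sum(!usable), " record(s) without positive measured GFR excluded")
    cohort <- gfr_cohort(as.data.frame(cohort)[usable, , drop = FALSE],
                         label = attr(cohort, "label"),
                         creatinine_unit = cohort_unit(cohort))
  }
  rows <- lapply(names(registry), function(label) {
    est <- tryCatch(registry[[label]](cohort), error = function(e) NULL)
    base <- data.frame(model = label, n = nrow(cohort))
    if (is.null(est) || all(is.na(est))) return(base)
    r <- cohort$measured_gfr - est
    ci <- rmse_with_ci(r, level = level)
    cbind(base,
          rmse = ci[["rmse"]], rmse_lwr = ci[["lwr"]], rmse_upr = ci[["upr"]],
          summarize_residuals(cohort$measured_gfr, est),
          dose_ape_gt_threshold = dose_error_fraction(
            cohort$measured_gfr, est, target_auc = target_auc,
            threshold = threshold))
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    need <- c("model", "n", "rmse", "rmse_lwr", "rmse_upr",
              "median_residual", "residual_q1", "residual_q3",
              "median_pe", "pe_q1", "pe_q3",
              "median_ape", "ape_q1", "ape_q3", "dose_ape_gt_threshold")
    for (cn in setdiff(need, names(r))) r[[cn]] <- NA_real_
    r[, need]
  }))
  out <- out[order(out$rmse), ]
  rownames(out) <- NULL
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Default model registry
#'
#' The seven published comparators, their four BSA-adjusted variants,
#' and (optionally) a fitted square-root GFR model labelled
#' `"new_model"`.
#'
#' @param fit Optional `sqrt_gfr_fit` to include.
#' @param black Race-factor flag for MDRD / CKD-EPI.
#' @return Named list of estimator functions for [compare_models].
#' @export
default_registry <- function(fit = NULL, black = FALSE) {
  reg <- list()
  for (m in comparator_specs()$model_id) {
    local({
      mm <- m
      reg[[mm]] <<- function(cohort) estimate_comparator(mm, cohort,
                                                         black = black)
    })
  }
  for (m in BSA_ADJUSTABLE) {
    local({
      mm <- m
      reg[[paste0(mm, "_bsa_adj")]] <<- function(cohort) {
        bsa_adjust(estimate_comparator(mm, cohort, black = black),
                   du_bois_bsa(cohort$height_cm, cohort$weight_kg),
                   model_id = mm)
      }
    })
  }
  if (!is.null(fit)) reg$new_model <- function(cohort) predict_gfr(fit, cohort)
  reg
}
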