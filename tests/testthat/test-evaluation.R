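test_that("RMSE and its chi-square interval match independent arithmetic", {
  r <- c(3, -4)
  out <- rmse_with_ci(r)
  expect_equal(unname(out["rmse"]), sqrt(12.5))
  expect_equal(unname(rmse_with_ci(rep(0, 10))), c(0, 0, 0))
  # chi-square quantiles via the Gamma(n/2, scale 2) identity
  set.seed(7)
  r2 <- rnorm(494, 0, 15)
  out2 <- rmse_with_ci(r2, level = 0.95)
  n <- length(r2)
  expect_equal(unname(out2["lwr"]),
               sqrt(sum(r2^2) / qgamma(0.975, shape = n / 2, scale = 2)),
               tolerance = 1e-8)
  expect_equal(unname(out2["upr"]),
               sqrt(sum(r2^2) / qgamma(0.025, shape = n / 2, scale = 2)),
               tolerance = 1e-8)
  expect_true(out2["lwr"] <= out2["rmse"] && out2["rmse"] <= out2["upr"])
  expect_error(rmse_with_ci(numeric(0)), "at least 2")
})

test_that("the chi-square RMSE interval covers the true sigma at its nominal rate", {
  hits <- 0
  set.seed(11)
  for (i in 1:500) {
    r <- rnorm(494, 0, 15)
    ci <- rmse_with_ci(r)
    hits <- hits + (ci["lwr"] <= 15 && 15 <= ci["upr"])
  }
  expect_gte(hits / 500, 0.92)
  expect_lte(hits / 500, 0.98)
})

test_that("interval width shrinks with n at fixed empirical sigma", {
  set.seed(3)
  r <- rnorm(200, 0, 10)
  small <- rmse_with_ci(r[1:50])
  large <- rmse_with_ci(r)
  expect_lt((large["upr"] - large["lwr"]) / large["rmse"],
            (small["upr"] - small["lwr"]) / small["rmse"])
})

test_that("residual summaries follow the documented sign conventions", {
  m <- c(100, 80, 60)
  expect_equal(summarize_residuals(m, m)$median_residual, 0)
  expect_equal(summarize_residuals(m, m)$median_ape, 0)
  one <- summarize_residuals(100, 80)
  expect_equal(one$median_residual, 20)   # positive = underestimation
  expect_equal(one$median_pe, -20)        # negative = underestimation PE
  expect_equal(one$median_ape, 20)
  # 11-pair set against a sort-based brute-force median/IQR oracle
  set.seed(19)
  meas <- runif(11, 40, 120)
  est <- meas + rnorm(11, 0, 12)
  s <- summarize_residuals(meas, est)
  brute <- function(x) {
    sx <- sort(x)
    list(med = sx[6],  # odd length: exact middle order statistic
         q = quantile(x, c(.25, .75), names = FALSE))
  }
  br <- brute(meas - est)
  expect_equal(s$median_residual, br$med)
  expect_equal(c(s$residual_q1, s$residual_q3), br$q)
  bp <- brute(100 * (est - meas) / meas)
  expect_equal(s$median_pe, bp$med)
  expect_error(summarize_residuals(1:3, 1:2), "equal length")
})

test_that("Calvert doses are the AUC-scaled GFR plus 25 offset", {
  expect_equal(calvert_dose(75, 5), 500)
  expect_equal(calvert_dose(123, 0), 0)
  expect_equal(calvert_dose(81, 5), 530)  # at the cohort's median GFR
})

test_that("dose error fractions match brute-force enumeration and drop the AUC", {
  m <- c(100, 90)
  expect_equal(dose_error_fraction(m, m), 0)
  expect_equal(dose_error_fraction(100, 100.1), 0)
  set.seed(29)
  meas <- runif(20, 30, 130)
  est <- meas * runif(20, 0.6, 1.4)
  got <- dose_error_fraction(meas, est, target_auc = 5, threshold = 20)
  ape <- abs(5 * (est + 25) - 5 * (meas + 25)) / (5 * (meas + 25)) * 100
  expect_equal(got, 100 * sum(ape > 20) / 20)
  # AUC cancels; patient order does not matter
  expect_equal(dose_error_fraction(meas, est, target_auc = 2), got)
  o <- sample(20)
  expect_equal(dose_error_fraction(meas[o], est[o]), got)
  # dose APE differs from GFR APE because of the +25 offset
  expect_false(isTRUE(all.equal(
    got, dose_error_fraction(meas, est, on_gfr = TRUE))))
})

test_that("Bland-Altman limits follow the mean +/- 1.96 SD rule", {
  m <- c(100, 80, 67, 45)
  ba0 <- bland_altman_stats(m, m)
  expect_equal(ba0$mean_difference, 0)
  expect_equal(ba0$lower_limit, 0)
  expect_equal(ba0$upper_limit, 0)
  # constant offset: difference = measured - estimated = +10, SD 0
  ba <- bland_altman_stats(m, m - 10)
  expect_equal(ba$mean_difference, 10)
  expect_equal(ba$lower_limit, 10)
  set.seed(31)
  meas <- runif(10, 50, 120)
  est <- meas + rnorm(10, 2, 6)
  ba2 <- bland_altman_stats(meas, est)
  d <- meas - est
  expect_equal(ba2$mean_difference, mean(d))
  expect_equal(ba2$upper_limit, mean(d) + 1.96 * sd(d))
  expect_equal(ba2$points$mean, (meas + est) / 2)
  expect_error(bland_altman_stats(1, 1), "at least 2")
})

test_that("Bland-Altman limits contain about 95% of normal differences", {
  set.seed(37)
  meas <- runif(1e4, 50, 130)
  est <- meas + rnorm(1e4, 0, 9)
  ba <- bland_altman_stats(meas, est)
  inside <- mean(ba$points$difference >= ba$lower_limit &
                   ba$points$difference <= ba$upper_limit)
  expect_equal(inside, 0.95, tolerance = 0.011)
})

test_that("threshold classification uses strict inequalities and sums to n", {
  m <- c(30, 49, 50, 51, 90)
  perfect <- threshold_classification(m, m, cutoff = 50)
  expect_equal(perfect["<cutoff", ">=cutoff"], 0, ignore_attr = TRUE)
  expect_equal(perfect[">=cutoff", "<cutoff"], 0, ignore_attr = TRUE)
  expect_equal(perfect["<cutoff", "<cutoff"], 2, ignore_attr = TRUE)  # 50 is not below
  all_low <- threshold_classification(rep(60, 4), rep(40, 4), cutoff = 50)
  expect_equal(all_low[">=cutoff", "<cutoff"], 4, ignore_attr = TRUE)
  set.seed(41)
  meas <- runif(200, 20, 120)
  est <- meas + rnorm(200, 0, 15)
  tab <- threshold_classification(meas, est, 50)
  expect_equal(sum(tab), 200)
  expect_equal(tab["<cutoff", "<cutoff"], sum(meas < 50 & est < 50),
               ignore_attr = TRUE)
})

test_that("predictive-interval coverage responds to sigma and the cutoff location", {
  co <- simulate_cohort(cohort_sim_config(n = 300, seed = 51))
  fit <- fit_sqrt_gfr(co)
  huge <- fit
  huge$sigma2 <- 400
  expect_equal(pi_coverage(huge, co)$coverage, 1)
  out <- pi_coverage(fit, co, cutoff = 1e6)
  expect_equal(out$cutoff_containment, 0)
  expect_equal(out$n, 300)
})

test_that("model comparison ranks a perfect estimator first with zero errors", {
  co <- simulate_cohort(cohort_sim_config(n = 120, seed = 61))
  registry <- list(
    oracle = function(cohort) cohort$measured_gfr,
    biased = function(cohort) cohort$measured_gfr * 1.4,
    ckd_epi = function(cohort) estimate_comparator("ckd_epi", cohort)
  )
  rep <- compare_models(co, registry)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$model[1], "oracle")
  expect_equal(rep$rmse[1], 0)
  expect_equal(rep$dose_ape_gt_threshold[1], 0)
  expect_true(all(diff(rep$rmse) >= 0))
  # a failing registry entry yields an NA row, not an error
  registry$broken <- function(cohort) stop("boom")
  rep2 <- compare_models(co, registry)
  expect_equal(nrow(rep2), 4)
  expect_true(is.na(rep2$rmse[rep2$model == "broken"]))
})
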