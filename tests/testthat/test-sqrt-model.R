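test_that("design rows honour the model's structural identities", {
  f <- make_record(55, "F", 165, 62, 80)
  Xf <- build_design(f)
  expect_equal(unname(Xf[1, c("sex", "sex_age")]), c(0, 0))
  # creatinine of 88.42 umol/L is 1 mg/dL, so every log term vanishes
  one <- make_record(55, "M", 178, 82, 88.42)
  X1 <- build_design(one)
  expect_equal(unname(X1[1, c("lncre", "lncre2", "lncre3")]), c(0, 0, 0))
  # interaction columns are exact products
  co <- toy_cohort(n = 15, seed = 7)
  X <- build_design(co)
  expect_identical(X[, "sex_age"], X[, "sex"] * X[, "age"])
  expect_identical(X[, "age_bsa"], X[, "age"] * X[, "bsa"])
  expect_true(all(X[, "intercept"] == 1))
  expect_error(build_design(make_record(55, "M", 178, 82, -3)), "positive")
})

test_that("OLS fit matches an explicit normal-equations solve", {
  co <- toy_cohort(n = 12, seed = 31)
  fit <- fit_sqrt_gfr(co)
  X <- build_design(co)
  y <- sqrt(co$measured_gfr)
  beta_ne <- solve(crossprod(X), crossprod(X, y))[, 1]  # independent route
  expect_equal(fit$beta, beta_ne, tolerance = 1e-8)
  rss <- sum((y - X %*% beta_ne)^2)
  expect_equal(fit$sigma2, rss / (nrow(X) - ncol(X)), tolerance = 1e-10)
  # mean sqrt-scale residual is zero with an intercept present
  expect_lt(abs(mean(fit$residuals_sqrt)), 1e-10)
  # lm() agrees too
  lmfit <- lm(y ~ X - 1)
  expect_equal(unname(fit$beta), unname(coef(lmfit)), tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear term", {
  co <- toy_cohort(n = 30, seed = 6)
  co$sex <- "F"  # the male indicator column is identically zero
  expect_error(fit_sqrt_gfr(co), "collinear.*sex")
})

test_that("point prediction squares the clamped sqrt-scale mean", {
  co <- toy_cohort(n = 8, seed = 12)
  m <- published_model(flat_beta(9))
  expect_equal(predict_gfr(m, co), rep(81, 8))
  # male vs female differ by the male offset on the sqrt scale
  fit <- published_model(synthetic_truth_beta)
  male <- make_record(60, "M", 170, 75, 90)
  female <- make_record(60, "F", 170, 75, 90)
  diff_sqrt <- sqrt(predict_gfr(fit, male)) - sqrt(predict_gfr(fit, female))
  expect_equal(diff_sqrt,
               unname(synthetic_truth_beta["sex"] +
                      synthetic_truth_beta["sex_age"] * 60),
               tolerance = 1e-10)
  # extreme inputs clamp to zero rather than go negative
  sick <- make_record(90, "F", 150, 40, 2500)
  expect_message(p <- predict_gfr(fit, sick), "clamped")
  expect_identical(p, 0)
})

test_that("default coefficients give GFR strictly decreasing in creatinine", {
  fit <- published_model(synthetic_truth_beta)
  scr_mgdl <- seq(0.2, 10, by = 0.05)
  for (sex in c("M", "F")) {
    vals <- vapply(scr_mgdl, function(s) {
      predict_gfr(fit, make_record(60, sex, 172, 75, s, unit = "mg/dL"))
    }, numeric(1))
    pos <- vals > 0  # below the clamp the curve is constant at zero
    expect_true(all(diff(vals[pos]) < 0), info = sex)
  }
})

test_that("predictive intervals match the t-interval algebra and predict.lm", {
  co <- toy_cohort(n = 40, seed = 44)
  fit <- fit_sqrt_gfr(co)
  new <- toy_cohort(n = 10, seed = 45)
  ints <- predict_gfr_interval(fit, new, level = 0.95)
  expect_true(all(ints$lwr <= ints$fit & ints$fit <= ints$upr))
  expect_true(all(ints$lwr >= 0))
  # independent route: lm + predict(interval = "prediction") on sqrt scale
  dtrain <- as.data.frame(build_design(co)[, -1])
  dtrain$y <- sqrt(co$measured_gfr)
  lmfit <- lm(y ~ ., data = dtrain)
  dnew <- as.data.frame(build_design(new)[, -1])
  ref <- predict(lmfit, newdata = dnew, interval = "prediction", level = 0.95)
  expect_equal(sqrt(ints$lwr), unname(pmax(0, ref[, "lwr"])),
               tolerance = 1e-8)
  expect_equal(sqrt(ints$upr), unname(ref[, "upr"]), tolerance = 1e-8)
  # nesting: the 99% interval contains the 95% interval
  wide <- predict_gfr_interval(fit, new, level = 0.99)
  expect_true(all(wide$lwr <= ints$lwr & ints$upr <= wide$upr))
  # interval width grows with sigma2
  inflated <- fit
  inflated$sigma2 <- fit$sigma2 * 4
  fat <- predict_gfr_interval(inflated, new, level = 0.95)
  expect_true(all(fat$upr - fat$lwr >= ints$upr - ints$lwr))
})

test_that("a zero-variance error model degenerates to the point estimate", {
  fit <- published_model(synthetic_truth_beta, sigma2 = 0, n_obs = 1977,
                         xtx_inv = diag(0, 9))
  rec <- make_record(60, "M", 178, 80, 90)
  ints <- predict_gfr_interval(fit, rec)
  expect_equal(ints$lwr, ints$fit)
  expect_equal(ints$upr, ints$fit)
})

test_that("threshold probabilities behave like a predictive t CDF", {
  fit <- fit_sqrt_gfr(simulate_cohort(cohort_sim_config(n = 300, seed = 5)))
  rec <- make_record(70, "F", 160, 58, 120)
  # cutoff at the point prediction gives probability one half
  point_sqrt <- as.numeric(build_design(rec, fit$terms) %*% fit$beta)
  expect_equal(prob_gfr_below(fit, rec, cutoff = point_sqrt^2), 0.5,
               tolerance = 1e-10)
  # monotone nondecreasing in the cutoff, limits 0 and 1
  cuts <- c(5, 20, 50, 80, 150, 500)
  probs <- vapply(cuts, function(cc) prob_gfr_below(fit, rec, cc), numeric(1))
  expect_true(all(diff(probs) >= 0))
  expect_gt(probs[6], 0.999)
  # complement identity via the t distribution's symmetry
  expect_equal(prob_gfr_below(fit, rec, 50) +
                 stats::pt((sqrt(50) - point_sqrt) /
                             sqrt(fit$sigma2 * (1 +
                               oncogfr:::sqrt_scale_pred(fit, rec)$leverage)),
                           df = fit$df_residual, lower.tail = FALSE),
               1, tolerance = 1e-12)
})

test_that("serialized models reproduce in-session predictions bit-for-bit", {
  co <- toy_cohort(n = 25, seed = 77)
  fit <- fit_sqrt_gfr(co)
  path <- withr::local_tempfile(fileext = ".json")
  write_gfr_model(fit, path)
  back <- read_gfr_model(path)
  new <- toy_cohort(n = 6, seed = 78)
  expect_identical(predict_gfr(back, new), predict_gfr(fit, new))
  expect_identical(predict_gfr_interval(back, new),
                   predict_gfr_interval(fit, new))
  expect_identical(prob_gfr_below(back, new, 50), prob_gfr_below(fit, new, 50))
})

test_that("coefficients-only models refuse interval requests clearly", {
  m <- published_model(synthetic_truth_beta)
  rec <- make_record(60, "M", 178, 80, 90)
  expect_silent(predict_gfr(m, rec))
  expect_error(predict_gfr_interval(m, rec), "coefficients only")
  expect_error(prob_gfr_below(m, rec, 50), "coefficients only")
})
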