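#' Model development machinery
#'
#' @description
#' Tools that reproduce the development pipeline of the square-root GFR
#' model on any cohort with measured GFR: Box-Cox response-scale
#' selection, three model-selection criteria (BIC, leave-one-out CV via
#' the leverage shortcut, seeded k-fold CV), forward stepwise search
#' from the intercept-only null model under a term-hierarchy constraint,
#' modal selection over repeated runs, and regression diagnostics
#' (Cook's distances, a Breusch-Pagan heteroscedasticity test).
#'
#' @name model_selection
NULL

#' Default candidate term pool
#'
#' Age, BSA, height, weight, sex, the three log-creatinine powers and
#' the two interactions. The pool is configuration: pass any subset or
#' extension to the selection functions.
#' @export
default_term_pool <- c("age", "bsa", "height", "weight", "sex",
                       "lncre", "lncre2", "lncre3", "sex_age", "age_bsa")

# Lower-order parents each term requires before it may enter a model.
TERM_PARENTS <- list(
  lncre2 = "lncre",
  lncre3 = c("lncre", "lncre2"),
  sex_age = c("sex", "age"),
  age_bsa = c("age", "bsa")
)

term_admissible <- function(term, current) {
  parents <- TERM_PARENTS[[term]]
  is.null(parents) || all(parents %in% current)
}

spec_satisfies_hierarchy <- function(terms) {
  all(vapply(terms, term_admissible, logical(1), current = terms))
}

#' Box-Cox response-transformation selection
#'
#' Profiles the Box-Cox log-likelihood of the linear model for the raw
#' (untransformed) measured GFR over a lambda grid and returns the
#' maximiser. A lambda near 0.5 supports the square-root response scale.
#'
#' @param cohort A [gfr_cohort] with positive `measured_gfr`.
#' @param terms Design terms for the profiled linear model.
#' @param grid Lambda grid to profile over.
#' @return List with `lambda` (the argmax), `grid` and `loglik`.
#' @export
box_cox_lambda <- function(cohort, terms = EQ_TERMS,
                           grid = seq(-1, 2, by = 0.02)) {
  if (any(is.na(cohort$measured_gfr)) || any(cohort$measured_gfr <= 0)) {
    stop("Box-Cox requires positive measured_gfr for every record",
         call. = FALSE)
  }
  if (stats::var(cohort$measured_gfr) == 0) {
    stop("degenerate response: measured_gfr has zero variance",
         call. = FALSE)
  }
  X <- build_design(cohort, terms)
  y <- cohort$measured_gfr
  bc <- MASS::boxcox(y ~ X - 1, lambda = grid, plotit = FALSE)
  list(lambda = bc$x[which.max(bc$y)], grid = bc$x, loglik = bc$y)
}

fit_terms <- function(cohort, terms) {
  X <- build_design(cohort, terms)
  y <- sqrt(cohort$measured_gfr)
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(NULL)  # rank-deficient candidate
  beta <- qr.coef(qx, y)
  resid <- as.numeric(y - X %*% beta)
  h <- rowSums(qr.Q(qx)^2)
  list(X = X, y = y, beta = beta, resid = resid, h = h,
       rss = sum(resid^2), n = nrow(X), p = ncol(X))
}

#' Score a candidate model under one selection criterion
#'
#' All scores are on the square-root-GFR scale; lower is better.
#' `bic = n * ln(RSS/n) + p * ln(n)` (constant terms dropped, so scores
#' compare only within one cohort); `loocv` is PRESS/n via the leverage
#' shortcut `sum((r_i / (1 - h_i))^2) / n` with no refitting loop;
#' `kfold` is the mean held-out squared error over a seeded random
#' partition into `k` folds.
#'
#' @param cohort A [gfr_cohort] with `measured_gfr`.
#' @param terms Candidate design terms (intercept implicit).
#' @param criterion `"bic"`, `"loocv"` or `"kfold"`.
#' @param k Number of folds for `"kfold"`.
#' @param seed Seed for the fold partition (required for `"kfold"`).
#' @return Scalar score (lower is better).
#' @export
criterion_score <- function(cohort, terms, criterion = c("bic", "loocv", "kfold"),
                            k = 5, seed = 1L) {
  criterion <- match.arg(criterion)
  if (criterion != "kfold") {
    ft <- fit_terms(cohort, terms)
    if (is.null(ft)) stop("rank-deficient design for terms: ",
                          paste(terms, collapse = ", "), call. = FALSE)
    return(switch(criterion,
      bic = ft$n * log(ft$rss / ft$n) + ft$p * log(ft$n),
      loocv = sum((ft$resid / (1 - ft$h))^2) / ft$n))
  }
  stopifnot(k >= 2)
  n <- nrow(cohort)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  sse <- 0
  for (f in seq_len(k)) {
    hold <- folds == f
    train <- gfr_cohort(as.data.frame(cohort)[!hold, , drop = FALSE],
                        creatinine_unit = cohort_unit(cohort))
    ft <- fit_terms(train, terms)
    if (is.null(ft)) stop("rank-deficient design in fold ", f, call. = FALSE)
    test <- gfr_cohort(as.data.frame(cohort)[hold, , drop = FALSE],
                       creatinine_unit = cohort_unit(cohort))
    Xh <- build_design(test, terms)
    pred <- as.numeric(Xh %*% ft$beta)
    sse <- sse + sum((sqrt(test$measured_gfr) - pred)^2)
  }
  sse / n
}

#' Forward stepwise term selection from the null model
#'
#' Greedy search: starting from the intercept-only model, at each step
#' the admissible candidate (hierarchy: polynomial and interaction terms
#' need their lower-order parents first) that most improves the
#' criterion is added; the search stops when no addition improves. Ties
#' are broken by pool order. With `backward = TRUE` each addition is
#' followed by removal passes that drop any term (hierarchy permitting)
#' whose removal improves the criterion.
#'
#' @inheritParams criterion_score
#' @param pool Candidate terms in documented order.
#' @param backward Also allow deletion steps (default forward-only).
#' @return Character vector of selected terms (`character(0)` is the
#'   null model), in order of entry.
#' @export
stepwise_select <- function(cohort, pool = default_term_pool,
                            criterion = "bic", k = 5, seed = 1L,
                            backward = FALSE) {
  current <- character(0)
  best <- criterion_score(cohort, current, criterion, k = k, seed = seed)
  repeat {
    candidates <- setdiff(pool, current)
    candidates <- candidates[vapply(candidates, term_admissible, logical(1),
                                    current = current)]
    if (length(candidates) == 0) break
    scores <- vapply(candidates, function(tm) {
      tryCatch(criterion_score(cohort, c(current, tm), criterion,
                               k = k, seed = seed),
               error = function(e) Inf)
    }, numeric(1))
    if (min(scores) >= best) break
    pick <- candidates[which.min(scores)]  # which.min: earliest tie wins
    current <- c(current, pick)
    best <- min(scores)
    if (backward && length(current) > 1) {
      repeat {
        removable <- current[vapply(current, function(tm) {
          spec_satisfies_hierarchy(setdiff(current, tm))
        }, logical(1))]
        drop_scores <- vapply(removable, function(tm) {
          tryCatch(criterion_score(cohort, setdiff(current, tm), criterion,
                                   k = k, seed = seed),
                   error = function(e) Inf)
        }, numeric(1))
        if (length(drop_scores) == 0 || min(drop_scores) >= best) break
        current <- setdiff(current, removable[which.min(drop_scores)])
        best <- min(drop_scores)
      }
    }
  }
  current
}

# Deterministic child-seed fan-out for repeated runs (kept below 2^31).
child_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1009 + 7919 * as.numeric(index)) %%
               2147483647)
}

#' Repeated stepwise selection with modal-model reporting
#'
#' Runs the stepwise search `reps` times, each with an independent
#' seeded fold partition (child seeds derived deterministically from the
#' master seed), and reports the frequency table of selected term sets
#' and the modal set — the repeated-selection scheme used to stabilise
#' cross-validation-based selection.
#'
#' @inheritParams stepwise_select
#' @param reps Number of repetitions (>= 1).
#' @return List of class `selection_report`: `modal_terms`, `frequency`
#'   (named integer vector over canonical term-set strings, summing to
#'   `reps`), `criterion`, `seeds`.
#' @export
repeated_selection <- function(cohort, reps = 100, pool = default_term_pool,
                               criterion = "kfold", k = 5, seed = 1L) {
  stopifnot(reps >= 1)
  seeds <- vapply(seq_len(reps), child_seed, integer(1), master = seed)
  keys <- character(reps)
  specs <- vector("list", reps)
  for (i in seq_len(reps)) {
    sel <- stepwise_select(cohort, pool = pool, criterion = criterion,
                           k = k, seed = seeds[i])
    specs[[i]] <- sel
    keys[i] <- paste(sort(sel), collapse = "+")
  }
  tab <- sort(table(keys), decreasing = TRUE)
  modal_key <- names(tab)[1]
  modal_terms <- specs[[match(modal_key, keys)]]
  structure(list(modal_terms = modal_terms,
                 frequency = as.integer(tab),
                 frequency_names = names(tab),
                 criterion = criterion, k = k,
                 reps = reps, seeds = seeds),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d repetitions, criterion = %s\n",
              x$reps, x$criterion))
  cat(sprintf("modal model (%d/%d): %s\n", x$frequency[1], x$reps,
              if (length(x$modal_terms)) paste(x$modal_terms, collapse = " + ")
              else "(null model)"))
  invisible(x)
}

#' Regression diagnostics for a fitted model
#'
#' Cook's distances from the standard residual/leverage formula
#' `r_i^2 h_i / (p s^2 (1 - h_i)^2)`, plus a Breusch-Pagan
#' heteroscedasticity test: the auxiliary regression of squared
#' residuals on the design gives statistic `n R^2 ~ chi^2(p - 1)` under
#' homoscedasticity.
#'
#' @param model A fitted `sqrt_gfr_fit` (from [fit_sqrt_gfr] on this
#'   cohort).
#' @param cohort The cohort the model was fitted on.
#' @param cooks_threshold Flag records with Cook's distance above this.
#' @return List: `cooks` (per-record distances), `max_cooks`,
#'   `flagged` (record indices), `bp_statistic`, `bp_df`, `bp_p_value`.
#' @export
regression_diagnostics <- function(model, cohort, cooks_threshold = 0.5) {
  require_error_model(model)
  X <- build_design(cohort, model$terms)
  y <- sqrt(cohort$measured_gfr)
  resid <- as.numeric(y - X %*% model$beta)
  h <- rowSums((X %*% model$xtx_inv) * X)
  p <- model$p
  s2 <- model$sigma2
  cooks <- resid^2 * h / (p * s2 * (1 - h)^2)
  # Breusch-Pagan auxiliary regression of r^2 on the design
  u <- resid^2
  aux <- stats::lm.fit(X, u)
  r2 <- 1 - sum(aux$residuals^2) / sum((u - mean(u))^2)
  stat <- length(u) * r2
  df <- p - 1
  list(cooks = cooks, max_cooks = max(cooks),
       flagged = which(cooks > cooks_threshold),
       bp_statistic = stat, bp_df = df,
       bp_p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
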