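---
title: "Methods: the square-root GFR model, its development machinery, and the synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the square-root GFR model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncogfr)
```

## The model and its assumptions

GFR in adult oncology cohorts is right-skewed and its variance grows
with its mean, so an untransformed linear model violates both
normality and homoscedasticity. The package models the *square root*
of measured GFR — the Box-Cox choice, which `box_cox_lambda()`
reproduces on any cohort — as a linear function of:

* age (years) and Du Bois body surface area (m²), each approximately
  linear on the √ scale;
* a cubic polynomial in ln(creatinine): the creatinine–GFR
  relationship is strongly nonlinear, the log transform does most of
  the work, and the quadratic and cubic terms absorb the remaining
  curvature;
* a male indicator with a male-by-age interaction (the sex gap in
  creatinine generation narrows with age) and an age-by-BSA
  interaction.

Errors are assumed independent, mean zero, normal, with constant
variance σ² *on the √ scale*. Everything downstream leans on that
assumption: predictive intervals use
`βᵀx ± t_{n−p} √(σ²(1 + xᵀ(XᵀX)⁻¹x))` squared back to mL/min, and
threshold probabilities use the same predictive t distribution. The
Breusch-Pagan diagnostic in `regression_diagnostics()` is the check
that the constant-variance assumption holds for a given fit.

Design choices where the design was genuinely open:

* **t rather than normal quantiles** for intervals, since σ is
  estimated; at development sample sizes (n ≈ 2,000) the difference is
  negligible, but the t version is exact under the model.
* **No retransformation (smearing) correction** by default: the point
  estimate is the squared √-scale mean. The corrected estimate
  `ŷ² + σ²(1 + leverage)` is available via `predict_gfr(smearing =
  TRUE)` but off by default; the uncorrected estimate targets the
  median of the predictive distribution, which is the clinically
  familiar quantity.
* **Clamping at zero**: a √-scale mean or interval endpoint below 0 is
  clamped before squaring (possible only for extreme covariates);
  occurrences are reported via a message.
* **Degraded coefficients-only mode**: `published_model()` builds a
  model object from a coefficient vector alone. Point prediction
  works; interval and probability requests raise a capability error
  unless σ², n, and the cross-product inverse are supplied — the
  machinery refuses to fake uncertainty it does not have.

## Units

Cohorts carry creatinine in µmol/L (UK laboratory convention) as the
single canonical unit; every equation converts centrally
(`convert_creatinine()`, factor 88.42). The √-model coefficients
assume mg/dL internally — recorded in the model object's
`creatinine_unit` field — because the log-creatinine polynomial is
centred near 0 on that scale. US-unit comparator formulas receive
mg/dL, UK-unit formulas (Wright, Martin) µmol/L, as declared per
formula in `comparator_specs()`.

## The synthetic-cohort generator

No patient-level data ship with the package; `simulate_cohort()`
generates cohorts from the same generative structure the model
assumes: covariates from per-sex distributions, then
`measured_gfr = (max(0, βᵀx + N(0, σ_√)))²`.

The defaults are calibrated once, to the published cohort summaries a
simulated study should reproduce:

| quantity | default | rationale |
|---|---|---|
| n | 2,471 | full-cohort size; 4:1 split gives 1,977 / 494 |
| age | truncated normal (62, 12) on [18, 95] | oncology case mix |
| height, weight | N(176, 7)/N(163, 7) cm; truncN(80, 15)/(70, 15) kg, min 35 | per-sex anthropometry |
| creatinine | log-normal, median 90 (M) / 75 (F) µmol/L, sdlog 0.45 | near-normal renal function with a renal-impairment tail |
| σ_√ | 0.83 | on the GFR scale the error of a correctly specified model is ≈ 2·√GFR·σ_√ ≈ 15 mL/min at √GFR ≈ 9, the regime the method is meant to operate in |
| days between measurements | rounded log-normal, median 6, cap 30 | the 30-day admission window with a realistic lag profile |

With these defaults a large simulated cohort has median measured GFR
81 mL/min with quartiles near 59–106, and the external-style seminoma
generator (`simulate_seminoma_cohort()`: all male, age ≈ 39.5 ± 9.6,
lower creatinine) has median GFR ≈ 113 mL/min at median age ≈ 39.

The ground-truth coefficient vector `synthetic_truth_beta` is
**synthetic**: it is not a published coefficient set and must not be
used for clinical estimation. It was designed once under three
constraints: (i) the cohort summaries above; (ii) every model term
carries an effect detectable at n ≈ 1,977 with σ_√ = 0.83 — in
particular the two age-scaled interactions (male×age, age×BSA) are
strongly collinear, and weak versions of either mask the other during
forward selection, so both were given effects that survive single-term
entry; (iii) predicted GFR decreases strictly with creatinine across
0.2–10 mg/dL (the cubic is globally monotone there: its derivative's
discriminant is negative).

What the generator deliberately does *not* emulate: the empirical
joint distribution of any real cohort (covariate correlations such as
height–weight beyond the per-sex means, assay error in creatinine,
measurement error in ⁵¹Cr-EDTA clearance, site effects). Passing tests
therefore demonstrate that the machinery is correct under its own
assumptions — not that the model is clinically valid, which only real
validation data can show.

## Model selection

`stepwise_select()` is a greedy forward search from the intercept-only
null model under a hierarchy constraint (a polynomial or interaction
term may enter only after all its lower-order parents). Three criteria
are available, all on the √ scale, lower better:

* **BIC** = n·ln(RSS/n) + p·ln(n), constant terms dropped (scores are
  comparable only within one cohort);
* **LOOCV** = PRESS/n via the leverage shortcut
  `Σ(rᵢ/(1−hᵢ))²/n` — exact, no refitting loop;
* **five-fold CV** with a seeded random partition;
  `repeated_selection()` reruns it with deterministically derived
  child seeds and reports the modal term set, the scheme that
  stabilises the randomness of fold assignment.

The search is forward-only by default (a deletion pass exists behind
`backward = TRUE`). Ties break by pool order. A practical note on the
criteria: BIC's entry threshold (t² > ln n ≈ 7.6) keeps noise terms
out with high probability, so under an intercept-only truth it returns
the null model in well over 90% of runs; the cross-validation criteria
are AIC-like and admit a spurious term in a nontrivial fraction of
runs — which is precisely why the modal-model scheme over repetitions
exists, and why the package's null-recovery guarantee is stated for
BIC.

The candidate pool is configuration (`default_term_pool`), not
hard-coded: age, BSA, height, weight, sex, the three ln-creatinine
powers, and the two interactions. Height and weight are conditionally
redundant given BSA under the generative truth, making them natural
in-pool noise probes.

The Breusch-Pagan statistic is the studentized (Koenker) form
n·R² from the auxiliary regression of squared residuals on the design,
χ²(p−1) under homoscedasticity; the published analysis of this model
family assessed heteroscedasticity graphically, and the test is this
package's quantitative replacement.

## Evaluation framework

Sign conventions (stated in every report): residual = measured −
estimated, so positive medians mean *under*estimation; percentage
error = 100·(estimated − measured)/measured, so negative median PE
means *under*estimation too. APE = |PE|. The PE denominator is the
measured value (standard practice; the alternative is not printed in
the source literature). RMSE confidence intervals use the χ² pivot
with n degrees of freedom. Carboplatin dose errors are computed on
Calvert doses — the +25 mL/min offset makes dose APE systematically
smaller than GFR APE — with strict inequality at the 20% boundary, and
strict `<` at the 50 mL/min cisplatin threshold. Bland-Altman limits
are mean ± 1.96 SD of the differences; box-plot notch half-widths, when
plot data are exported, are 1.58·IQR/√n. `compare_models()` orders its
report by ascending RMSE and excludes (with a message) any record
whose measured GFR is not positive, since PE is undefined there — the
generator's clamp rule can produce such records at a ≈ 10⁻⁴ rate.

## Numerical choices

* OLS via QR; the cross-product inverse is kept for leverage and
  interval computation, and rank deficiency fails loudly naming the
  collinear columns.
* Model JSON stores doubles as `%.17g` strings because JSON writers
  round at 15 significant digits; reloading a saved model reproduces
  predictions bit for bit.
* The split rule rounds `ratio·n` half away from zero, so 2,471
  patients at 0.8 give exactly 1,977/494.
* Seeded helpers (`split_cohort`, `simulate_cohort`, k-fold
  partitions) save and restore the caller's RNG state; repetition
  child seeds are an affine map of the master seed kept below 2³¹.

## Problem sizes used in the checks

The shipped checks run at deliberately modest scale: oracle
equivalence on 12–30-record cohorts; parameter recovery and selection
studies at the development size n = 1,977 with 100 replicates;
interval calibration on 10,000 fresh patients with 10⁵ Monte-Carlo
draws; the repeated-selection report at 50 repetitions in the pipeline
script (the stabilisation plateau is reached well before the published
2,000). The 100-partition robustness study of the source analysis is
represented by the 100-replicate selection property, not a default
pipeline stage.

## Known limitations

* The synthetic truth is a stand-in; nothing here validates clinical
  accuracy on real patients.
* Race adjustment factors are implemented for MDRD/CKD-EPI but default
  to the non-black coefficient, matching the white-only development
  population of the source cohorts; cystatin C and other covariates
  are out of scope.
* The cubic creatinine polynomial is monotone only over the declared
  calibration range; predictions outside ~0.2–10 mg/dL creatinine are
  extrapolations and the clamp message should be treated as a warning
  sign.
* Comparator formulas were transcribed from their primary references;
  the Jelliffe 1973 and Martin 1998 forms are the variants chosen
  where the literature has several, and swapping variants means
  editing one registry entry.
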