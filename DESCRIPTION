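Package: oncogfr
Title: Glomerular Filtration Rate Estimation and Carboplatin Dosing for
    Patients with Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of glomerular filtration rate (GFR) in adult
    oncology cohorts. Implements a linear model on the square-root GFR
    scale with cubic log-creatinine terms, per-patient predictive
    intervals and threshold probabilities for cisplatin decision support,
    alongside seven published creatinine-based eGFR equations
    (Cockcroft-Gault, Jelliffe, Wright, Martin, Mayo quadratic, MDRD,
    CKD-EPI) with optional body-surface-area adjustment. Includes the
    full model-development machinery (Box-Cox response-scale selection,
    forward stepwise search under BIC, leave-one-out and k-fold
    cross-validation, repeated modal selection, regression diagnostics),
    carboplatin dose-error analysis via the Calvert equation, agreement
    statistics (RMSE with chi-square confidence intervals, Bland-Altman
    limits, percentage errors), and a calibrated synthetic-cohort
    simulator so every stage is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    withr
Config/testthat/edition: 3
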