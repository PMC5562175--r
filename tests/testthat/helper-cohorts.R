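# Shared fixture builders: every cohort is generated in code.

# Small deterministic cohort with measured GFR, creatinine in umol/L.
toy_cohort <- function(n = 12, seed = 101) {
  oncogfr:::with_seed(seed, {
    df <- data.frame(
      patient_id = sprintf("T%03d", seq_len(n)),
      age = round(runif(n, 20, 90), 1),
      sex = sample(c("M", "F"), n, replace = TRUE),
      height_cm = round(rnorm(n, 170, 8), 1),
      weight_kg = round(runif(n, 45, 110), 1),
      creatinine = round(rlnorm(n, log(80), 0.4), 1),
      measured_gfr = round(runif(n, 25, 140), 1),
      days_between = sample(0:20, n, replace = TRUE)
    )
    gfr_cohort(df, label = "toy", creatinine_unit = "umol/L")
  })
}

# One-record cohort from named fields.
make_record <- function(age, sex, height_cm, weight_kg, creatinine,
                        unit = "umol/L", measured_gfr = NA_real_) {
  gfr_cohort(data.frame(patient_id = "R1", age = age, sex = sex,
                        height_cm = height_cm, weight_kg = weight_kg,
                        creatinine = creatinine,
                        measured_gfr = measured_gfr),
             creatinine_unit = unit)
}

# Intercept-only truth coefficient vector on the model's term order.
flat_beta <- function(intercept = 9) {
  b <- setNames(numeric(length(oncogfr:::EQ_TERMS)), oncogfr:::EQ_TERMS)
  b["intercept"] <- intercept
  b
}
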