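# Shared fixtures, built in code at test time.

# Independence rows (one observation per subject) from a log-link risk model:
# risk = base * exp(beta * x). Used for GLM-equivalence and calibration tests.
make_independence_rows <- function(n, beta = 0, base = 0.2, seed = 1) {
  set.seed(seed)
  d <- tibble::tibble(
    subject_id = sprintf("s%05d", seq_len(n)),
    log2_value = rnorm(n, 0, 1.5),
    sex = factor(sample(c("male", "female"), n, replace = TRUE)),
    maternal_age = rnorm(n, 30, 5))
  d$status <- rbinom(n, 1, pmin(0.95, base * exp(beta * d$log2_value))) == 1
  d
}

# Prenatal-style analysis rows straight from the synthetic generator.
sim_prenatal_rows <- function(n = 1500, rr = 1.0, outcome = "asthma",
                              baseline = 0.146, gm = 0.90, gsd = 3.62,
                              seed = 1) {
  spec <- cohort_spec(n_subjects = n, period = "prenatal",
                      exposure_gm = c(DBP = gm), exposure_gsd = c(DBP = gsd),
                      outcome_baseline = stats::setNames(baseline, outcome),
                      true_rr = stats::setNames(list(c(DBP = rr)), outcome))
  sim <- suppressWarnings(simulate_cohort(spec, seed = seed))
  expo <- period_average(sim_exposure_records(sim))
  build_prenatal_table(expo, sim$outcomes, sim$covariates, "DBP", outcome,
                       covariate_names = c("sex", "maternal_age"))
}

# Lagged postnatal analysis rows: repeated exposures at 1/2/3 years, each
# aligned with the outcomes in its following window.
sim_postnatal_rows <- function(n = 1700, analyte = "MCPP", gm = 1.31,
                               gsd = 2.72, outcome = "wheeze",
                               baseline = 0.598, rr = 1.0, seed = 1) {
  spec <- cohort_spec(
    n_subjects = n, period = "postnatal",
    exposure_gm = stats::setNames(gm, analyte),
    exposure_gsd = stats::setNames(gsd, analyte),
    outcome_baseline = stats::setNames(baseline, outcome),
    true_rr = stats::setNames(list(stats::setNames(rr, analyte)), outcome))
  sim <- suppressWarnings(simulate_cohort(spec, seed = seed))
  expo <- sim_exposure_records(sim, scale = "concentration")
  build_postnatal_table(expo, sim$outcomes, sim$covariates, analyte, outcome,
                        covariate_names = c("sex", "maternal_age"))
}

# Minimal urine-sample table for the standardization tests.
make_urine_samples <- function(n = 50, seed = 1, lod = 0) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    cohort_id = "T",
    sampling_time = 36,
    analyte = "MnBP",
    concentration = rlnorm(n, log(5), 0.8),
    censored = FALSE,
    lod = lod,
    specific_gravity = 1 + runif(n, 0.005, 0.04),
    creatinine = rlnorm(n, log(100), 0.4),
    batch = sample(c("A", "B"), n, replace = TRUE),
    clock_time = runif(n, 7, 20))
}
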