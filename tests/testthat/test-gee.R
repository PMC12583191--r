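test_that("with cluster size 1 the GEE equals a robust Poisson GLM", {
  d <- make_independence_rows(600, beta = 0.2, seed = 12)
  f <- fit_gee(d, status ~ log2_value + sex + maternal_age, id = "subject_id")
  g <- stats::glm(status ~ log2_value + sex + maternal_age, data = d,
                  family = stats::poisson())
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
  V <- sandwich::vcovCL(g, cluster = d$subject_id, type = "HC0",
                        cadjust = FALSE)
  expect_equal(max(abs(vcov(f) - V)), 0, tolerance = 1e-6)
  expect_equal(f$alpha, 0)
  expect_true(f$converged)
})

test_that("risk ratios per doubling follow the log2 coefficient map", {
  expect_equal(rr_per_doubling(0), 1)
  expect_equal(rr_per_doubling(log(1.08)), 1.08)
  # quadrupling multiplies fitted risk by RR squared
  b <- log(1.3)
  expect_equal(exp(2 * b), rr_per_doubling(b)^2)
})

test_that("adding a constant to log2 exposure changes only the intercept", {
  d <- make_independence_rows(800, beta = 0.15, seed = 3)
  f1 <- fit_gee(d, status ~ log2_value + sex, id = "subject_id")
  d2 <- dplyr::mutate(d, log2_value = log2_value + 5)
  f2 <- fit_gee(d2, status ~ log2_value + sex, id = "subject_id")
  expect_equal(coef(f1)[["log2_value"]], coef(f2)[["log2_value"]],
               tolerance = 1e-8)
  expect_equal(effect_estimate(f1)$rr, effect_estimate(f2)$rr,
               tolerance = 1e-8)
})

test_that("exchangeable alpha picks up within-subject outcome dependence", {
  spec <- cohort_spec(n_subjects = 1200, period = "prenatal",
                      exposure_gm = c(A = 1), exposure_gsd = c(A = 3),
                      outcome_baseline = c(wheeze = 0.4), frailty_sd = 0.6)
  sim <- suppressWarnings(simulate_cohort(spec, seed = 17))
  expo <- period_average(sim_exposure_records(sim))
  rows <- build_prenatal_table(expo, sim$outcomes, sim$covariates, "A", "wheeze",
                               covariate_names = c("sex", "maternal_age"))
  f <- fit_gee(rows, status ~ log2_value + sex, id = "subject_id")
  expect_gt(f$alpha, 0.05)
})

test_that("biomarker- and intake-scale fits agree up to a constant factor", {
  d <- make_independence_rows(700, beta = 0.2, seed = 8)
  f_bio <- fit_gee(d, status ~ log2_value + sex, id = "subject_id")
  # intake = constant multiple of the biomarker => log2 shift only
  d_edi <- dplyr::mutate(d, log2_value = log2_value + log2(3.7))
  f_edi <- fit_gee(d_edi, status ~ log2_value + sex, id = "subject_id")
  expect_equal(effect_estimate(f_bio)$rr, effect_estimate(f_edi)$rr,
               tolerance = 1e-8)
})

test_that("the spline curve is 1 at its reference and flags curvature", {
  # U-shaped (quadratic) truth is detected at n = 2000
  set.seed(33)
  n <- 2000
  d <- tibble::tibble(subject_id = sprintf("s%04d", 1:n),
                      log2_value = rnorm(n, 0, 1.5),
                      sex = factor(sample(c("m", "f"), n, TRUE)))
  d$status <- rbinom(n, 1, pmin(0.9, 0.15 * exp(0.12 * d$log2_value^2))) == 1
  dr <- fit_dose_response(d, status ~ sex)
  expect_lt(dr$p_nonlinearity, 0.05)
  ref_rr <- dr$curve$rr[which.min(abs(dr$curve$exposure - dr$reference))]
  expect_equal(ref_rr, 1, tolerance = 0.05)
  expect_true(all(dr$curve$ci_low <= dr$curve$rr & dr$curve$rr <= dr$curve$ci_high))
  expect_error(rcs_basis(rep(1, 10)), "knots")
})

test_that("sex interaction contrasts equal stratified fits at cluster size 1", {
  d <- make_independence_rows(900, beta = 0.2, seed = 5)
  # only the exposure and sex in the model: the fully interacted model
  # factorizes into per-stratum fits
  emm <- fit_sex_emm(d, status ~ log2_value + sex)
  lv <- levels(d$sex)
  per_sex <- purrr::map_dbl(lv, function(s) {
    g <- stats::glm(status ~ log2_value, data = d[d$sex == s, ],
                    family = stats::poisson())
    exp(coef(g)[["log2_value"]])
  })
  expect_equal(emm$estimates$rr, per_sex, tolerance = 1e-6)
  expect_true(emm$p_interaction >= 0 && emm$p_interaction <= 1)
  expect_error(fit_sex_emm(d[d$sex == lv[1], ], status ~ log2_value + sex),
               "both sexes")
})

test_that("an effect injected in one sex only is detected", {
  set.seed(44)
  n <- 4000
  d <- tibble::tibble(subject_id = sprintf("s%04d", 1:n),
                      log2_value = rnorm(n, 0, 1.5),
                      sex = factor(sample(c("female", "male"), n, TRUE)))
  b <- ifelse(d$sex == "female", 0.25, 0)
  d$status <- rbinom(n, 1, pmin(0.9, 0.2 * exp(b * d$log2_value))) == 1
  emm <- fit_sex_emm(d, status ~ log2_value + sex)
  rr_f <- emm$estimates$rr[emm$estimates$sex == "female"]
  rr_m <- emm$estimates$rr[emm$estimates$sex == "male"]
  expect_gt(rr_f, rr_m)
  expect_lt(emm$p_interaction, 0.05)
})

test_that("trimester stratification isolates a first-trimester effect", {
  set.seed(55)
  n <- 1500
  subj <- sprintf("s%04d", 1:n)
  # per-trimester exposures, independent across trimesters
  expo <- tidyr::expand_grid(subject_id = subj, trimester = 1:3) |>
    dplyr::mutate(cohort_id = "T", parent_code = "BPS", period = "prenatal",
                  scale = "edi", value = rlnorm(dplyr::n(), 0, 1),
                  log2_value = log2(value))
  # outcome driven by trimester-1 exposure only
  x1 <- expo$log2_value[expo$trimester == 1][match(subj, expo$subject_id[expo$trimester == 1])]
  oc <- tibble::tibble(subject_id = subj, outcome = "asthma",
                       age_at_assessment = 2,
                       status = rbinom(n, 1, pmin(0.9, 0.15 * exp(0.4 * x1))) == 1)
  cv <- tibble::tibble(subject_id = subj,
                       sex = factor(sample(c("m", "f"), n, TRUE)))
  tr_tabs <- dplyr::mutate(expo)  # already per-trimester
  fits <- fit_by_trimester(tr_tabs, oc, cv, "BPS", "asthma",
                           status ~ log2_value + sex,
                           covariate_names = "sex")
  expect_equal(nrow(fits), 3)
  rr1 <- fits$rr[fits$trimester == 1]
  expect_gt(rr1, 1.2)
  expect_true(all(abs(log(fits$rr[fits$trimester != 1])) < log(1.15)))
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- make_independence_rows(300, beta = 0.2, seed = 2)
  f <- fit_gee(d, status ~ log2_value + sex, id = "subject_id")
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "robust_se", "p.value",
                    "conf.low", "conf.high") %in% names(td)))
  expect_equal(nrow(td), 3)
  te <- tidy(f, exponentiate = TRUE)
  expect_equal(te$estimate, exp(td$estimate))
  gl <- glance(f)
  expect_identical(gl$n_clusters, 300L)
  expect_true(gl$converged)
})
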