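test_that("the E-value formula behaves as the theory requires", {
  expect_equal(evalue(1)$evalue_point, 1)
  # symmetric in the null: protective estimates are inverted first
  expect_equal(evalue(0.8)$evalue_point, evalue(1.25)$evalue_point)
  # monotone increasing above 1
  rrs <- c(1.01, 1.1, 1.5, 2, 5)
  expect_true(all(diff(evalue(rrs)$evalue_point) > 0))
  # CI crossing the null gives 1; otherwise the nearer limit is used
  e <- evalue(1.08, ci_low = 1.00, ci_high = 1.16)
  expect_equal(e$evalue_ci, 1)
  e2 <- evalue(1.09, ci_low = 1.04, ci_high = 1.14)
  expect_equal(e2$evalue_ci, 1.04 + sqrt(1.04 * 0.04))
  expect_error(evalue(-1), "positive")
})

test_that("meta-analysis degenerates correctly and recovers tau2", {
  same <- tibble::tibble(cohort_id = c("a", "b", "c"),
                         log_rr = log(1.08), se = c(0.02, 0.03, 0.04))
  m <- random_effects_meta(same)
  expect_equal(m$tau2, 0, tolerance = 1e-8)
  expect_equal(m$i2, 0)
  expect_equal(m$pooled_rr, 1.08, tolerance = 1e-6)
  one <- random_effects_meta(same[1, ])
  expect_equal(one$pooled_rr, 1.08)
  expect_equal(one$tau2, 0)
  expect_error(random_effects_meta(dplyr::mutate(same, se = 0)), "positive")
  # REML recovers a known between-cohort variance
  set.seed(19)
  k <- 40
  se <- runif(k, 0.05, 0.15)
  d <- tibble::tibble(cohort_id = paste0("c", 1:k),
                      log_rr = rnorm(k, 0.1, sqrt(0.04 + se^2)), se = se)
  fit <- metafor::rma(yi = d$log_rr, sei = d$se, method = "REML")
  m2 <- random_effects_meta(d)
  expect_equal(m2$tau2, fit$tau2)
  expect_lt(abs(m2$tau2 - 0.04), 3 * fit$se.tau2)
  expect_gt(m2$i2, 50)
})

test_that("stabilized weights are near 1 under null selection", {
  set.seed(23)
  n <- 2000
  d <- tibble::tibble(z = rnorm(n), w2 = rnorm(n),
                      included = rbinom(n, 1, 0.6) == 1)
  w <- stabilized_ipw(d, "included", ~ z + w2)
  expect_equal(mean(w$ipw), 1, tolerance = 0.05)
  expect_lt(diff(range(w$ipw)), 0.5)
  dbad <- dplyr::mutate(d, included = z > 0)
  expect_error(stabilized_ipw(dbad, "included", ~ z), "perfect")
})

test_that("selection-weighted fits pull estimates back toward the cohort value", {
  set.seed(29)
  n <- 6000
  z <- rbinom(n, 1, 0.5)                    # effect modifier
  x <- rnorm(n, 0, 1.5)
  b <- ifelse(z == 1, 0.30, 0)              # exposure acts only when z = 1
  d <- tibble::tibble(subject_id = sprintf("s%05d", 1:n), z = z,
                      log2_value = x,
                      status = rbinom(n, 1, pmin(0.9, 0.15 * exp(b * x))) == 1)
  full <- fit_gee(d, status ~ log2_value, id = "subject_id")
  truth <- coef(full)[["log2_value"]]
  # selection strongly favours the z = 1 stratum
  d$included <- rbinom(n, 1, ifelse(z == 1, 0.9, 0.15)) == 1
  w <- stabilized_ipw(d, "included", ~ z)
  inc <- w
  naive <- fit_gee(inc, status ~ log2_value, id = "subject_id")
  weighted <- fit_gee(inc, status ~ log2_value, id = "subject_id",
                      weights = "ipw")
  err_naive <- abs(coef(naive)[["log2_value"]] - truth)
  err_w <- abs(coef(weighted)[["log2_value"]] - truth)
  expect_lt(err_w, err_naive)
})

test_that("chained-equation imputation is a no-op without missingness", {
  d <- make_independence_rows(300, beta = 0.2, seed = 31)
  pooled <- mice_pool(d, status ~ log2_value + sex + maternal_age,
                      m = 3, iterations = 2, seed = 1)
  complete <- fit_gee(d, status ~ log2_value + sex + maternal_age,
                      id = "subject_id")
  expect_equal(pooled$rr, exp(coef(complete)[["log2_value"]]), tolerance = 1e-12)
  expect_equal(pooled$between_var, 0)
  expect_equal(pooled$total_var, pooled$within_var)
})

test_that("MCAR covariate gaps leave the pooled estimate near complete-data", {
  d <- make_independence_rows(1500, beta = 0.25, seed = 37)
  complete <- fit_gee(d, status ~ log2_value + sex + maternal_age,
                      id = "subject_id")
  d2 <- d
  set.seed(38)
  d2$maternal_age[runif(1500) < 0.05] <- NA
  d2$sex[runif(1500) < 0.05] <- NA
  pooled <- mice_pool(d2, status ~ log2_value + sex + maternal_age,
                      m = 5, iterations = 5, seed = 2)
  se <- sqrt(complete$vcov["log2_value", "log2_value"])
  expect_lt(abs(log(pooled$rr) - coef(complete)[["log2_value"]]), 2 * se)
  # Rubin decomposition
  expect_gte(pooled$between_var, 0)
  expect_gte(pooled$total_var, pooled$within_var)
})

test_that("imputation warns on heavy missingness and rejects empty columns", {
  d <- tibble::tibble(a = c(rnorm(5), rep(NA, 6)), b = rnorm(11), c = rnorm(11))
  expect_warning(impute_covariates(d, m = 1, iterations = 1, exclude = character(0)),
                 "50%")
  d$a <- NA_real_
  expect_error(suppressWarnings(
    impute_covariates(d, m = 1, iterations = 1, exclude = character(0))),
    "no observed")
})

test_that("Rubin pooling combines estimates and variances correctly", {
  est <- c(0.1, 0.12, 0.08)
  v <- c(0.01, 0.011, 0.009)
  p <- pool_rubin(est, v)
  expect_equal(p$estimate, mean(est))
  expect_equal(p$within_var, mean(v))
  expect_equal(p$between_var, var(est))
  expect_equal(p$total_var, mean(v) + (1 + 1 / 3) * var(est))
})

test_that("DEHP restriction keeps the risk ratio when removal is proportional", {
  reg <- analyte_registry()
  set.seed(41)
  n <- 600
  subj <- sprintf("s%04d", 1:n)
  mehhp <- rlnorm(n, log(12), 1)
  mw <- reg$mw_metabolite[match(c("MEHP", "MEHHP"), reg$metabolite_code)]
  samples <- dplyr::bind_rows(
    tibble::tibble(subject_id = subj, cohort_id = "T", sampling_time = 26,
                   analyte = "MEHHP", concentration = mehhp, weight = 70),
    tibble::tibble(subject_id = subj, cohort_id = "T", sampling_time = 26,
                   # MEHP molar concentration proportional to MEHHP's
                   analyte = "MEHP", concentration = 0.5 * mehhp * mw[1] / mw[2],
                   weight = 70))
  expo <- period_average(derive_exposures(samples, "prenatal", registry = reg))
  oc <- tibble::tibble(subject_id = subj, outcome = "eczema",
                       age_at_assessment = 2,
                       status = rbinom(n, 1, pmin(0.9, 0.2 * exp(0.15 * scale(expo$log2_value)))) == 1)
  cv <- tibble::tibble(subject_id = subj,
                       sex = factor(sample(c("m", "f"), n, TRUE)))
  cmp <- compare_dehp_restriction(samples, oc, cv, "eczema",
                                  status ~ log2_value + sex,
                                  exclude = "MEHP", registry = reg)
  expect_equal(cmp$rr[cmp$set == "full"], cmp$rr[cmp$set == "restricted"],
               tolerance = 1e-8)
  expect_error(restrict_dehp_metabolites(samples, c("MEHP", "MEHHP"),
                                         registry = reg), "every measured")
})
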