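test_that("the intake equation reproduces hand arithmetic and its limits", {
  reg <- analyte_registry()
  # MnBP with literature constants: 50*1.6*278.34 / (0.69*70*222.24)
  expect_equal(compute_edi(50, "MnBP", weight = 70, uv = 1.6, registry = reg),
               (50 * 1.6 * 278.34) / (0.69 * 70 * 222.24))
  expect_equal(compute_edi(50, "MnBP", weight = 70, registry = reg),
               2.074, tolerance = 1e-3)
  # all ratios cancel: FUE = 1, MW_d = MW_m, UV = W numerically
  fake <- tibble::tibble(metabolite_code = "Z", parent_code = "Z",
                         mw_metabolite = 100, mw_parent = 100, fue = 1,
                         analyte_class = "phthalate", is_edi_eligible = TRUE)
  expect_equal(compute_edi(7, fake, weight = 1.6, uv = 1.6), 7)
  expect_error(compute_edi(5, "MCPP", weight = 70), "not-EDI|not EDI-eligible|eligible")
})

test_that("intake is linear in concentration and inverse in weight", {
  set.seed(2)
  for (i in 1:20) {
    c0 <- runif(1, 1, 100); w <- runif(1, 40, 100); k <- runif(1, 0.5, 4)
    e1 <- compute_edi(c0, "MEP", weight = w)
    expect_equal(compute_edi(k * c0, "MEP", weight = w), k * e1)
    expect_equal(compute_edi(c0, "MEP", weight = k * w), e1 / k)
  }
})

test_that("parent aggregation: molar sums, subsets, and the DBP sum rule", {
  reg <- analyte_registry()
  # single metabolite reduces to compute_edi
  expect_equal(aggregate_parent(c(MEP = 10), "DEP", weight = 70, registry = reg),
               compute_edi(10, "MEP", weight = 70, registry = reg))
  # equal molar concentrations double the molar sum
  one <- aggregate_parent(c(MEHHP = 294.34), "DEHP", weight = 70, registry = reg)
  # scale the second metabolite to the same molar concentration (1 umol/L)
  two <- aggregate_parent(c(MEHHP = 294.34, MEOHP = 292.33), "DEHP",
                          weight = 70, registry = reg)
  fue1 <- reg$fue[reg$metabolite_code == "MEHHP"]
  fue2 <- reg$fue[reg$metabolite_code == "MEOHP"]
  # with the combined-FUE convention: (2 umol * MW)/(fue1+fue2) vs 1 umol/fue1
  expect_equal(two, one * 2 * fue1 / (fue1 + fue2))
  # permutation invariance
  x <- c(MEHP = 5, MEHHP = 12, MEOHP = 9, MECPP = 20)
  expect_equal(aggregate_parent(x, "DEHP", weight = 60, registry = reg),
               aggregate_parent(rev(x), "DEHP", weight = 60, registry = reg))
  expect_error(aggregate_parent(c(MEP = 1), "DEHP", weight = 70, registry = reg),
               "parent")
  expect_error(aggregate_parent(setNames(numeric(0), character(0)), "DEHP",
                                weight = 70, registry = reg), "empty")
})

test_that("derive_exposures builds DBP from DiBP + DnBP and keeps MCPP as is", {
  reg <- analyte_registry()
  s <- tibble::tibble(
    subject_id = "a", cohort_id = "T", sampling_time = 36,
    analyte = c("MiBP", "MnBP", "MCPP"),
    concentration = c(10, 11, 3), weight = 70)
  out <- derive_exposures(s, "prenatal", registry = reg)
  dibp <- compute_edi(10, "MiBP", weight = 70, registry = reg)
  dnbp <- compute_edi(11, "MnBP", weight = 70, registry = reg)
  expect_equal(out$value[out$parent_code == "DBP"], dibp + dnbp)
  mcpp <- out[out$parent_code == "MCPP", ]
  expect_identical(mcpp$scale, "concentration")
  expect_equal(mcpp$value, 3)
  expect_equal(out$log2_value, log2(out$value))
})

test_that("pregnancy weight estimation follows the gain schedule monotonically", {
  w0 <- estimate_weight_at_sampling(65, 22, 0)
  expect_equal(w0, 65)
  w30 <- estimate_weight_at_sampling(65, 22, 30)
  w36 <- estimate_weight_at_sampling(65, 22, 36)
  expect_lte(w30, w36)
  # obese category gains less than underweight at the same week
  expect_lt(estimate_weight_at_sampling(90, 33, 36) - 90,
            estimate_weight_at_sampling(50, 17, 36) - 50)
  grid <- estimate_weight_at_sampling(65, 22, seq(0, 42, by = 2))
  expect_true(all(diff(grid) >= 0))
})

test_that("child urine volume lookup is piecewise constant and positive", {
  expect_equal(child_uv_per_weight(1.2), child_uv_per_weight(2.9))
  expect_true(all(child_uv_per_weight(c(0.5, 1.5, 4)) > 0))
  expect_error(child_uv_per_weight(7), "\\(0, 6\\)")
  # round-trips through serialized config
  tab <- child_uvw_table <- tibble::tibble(age_lower = c(0, 2),
                                           age_upper = c(2, 6),
                                           uv_per_kg = c(0.04, 0.02))
  tf <- tempfile(fileext = ".tsv")
  readr::write_tsv(tab, tf)
  tab2 <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(child_uv_per_weight(1, table = tab2),
               child_uv_per_weight(1, table = tab))
})

test_that("prenatal averaging is on the natural scale, then log2", {
  rec <- tibble::tibble(
    subject_id = "a", cohort_id = "T", parent_code = "DEP",
    period = "prenatal", timing = c(16, 26), value = c(2, 4),
    scale = "edi", log2_value = log2(c(2, 4)))
  avg <- period_average(rec)
  expect_equal(nrow(avg), 1)
  expect_equal(avg$value, 3)
  expect_equal(avg$log2_value, log2(3))
  expect_equal(avg$log2_value, 1.585, tolerance = 1e-3)
  # postnatal records pass through with counts preserved
  post <- dplyr::mutate(rec, period = "postnatal")
  expect_identical(period_average(post), post)
})

test_that("trimester binning uses the obstetric boundaries", {
  rec <- tibble::tibble(
    subject_id = c("a", "a", "a", "b"), cohort_id = "T", parent_code = "DEP",
    period = "prenatal", timing = c(10, 12, 36, 20), value = c(2, 4, 8, 5),
    scale = "edi", log2_value = log2(c(2, 4, 8, 5)))
  tr <- trimester_average(rec)
  a1 <- tr[tr$subject_id == "a" & tr$trimester == 1, ]
  expect_equal(a1$value, 3)  # weeks 10 and 12 averaged
  expect_equal(tr$trimester[tr$subject_id == "a" & tr$value == 8], 3L)
  # subject b has no trimester-1 or -3 rows
  expect_identical(tr$trimester[tr$subject_id == "b"], 2L)
})

test_that("doubling all concentrations shifts log2 exposure by exactly one", {
  reg <- analyte_registry()
  s <- tibble::tibble(
    subject_id = "a", cohort_id = "T", sampling_time = 36,
    analyte = c("MEHP", "MEHHP", "MEOHP", "MECPP", "MEP", "MCPP"),
    concentration = c(5, 12, 9, 20, 30, 3), weight = 70)
  s2 <- dplyr::mutate(s, concentration = concentration * 2)
  a <- derive_exposures(s, "prenatal", registry = reg)
  b <- derive_exposures(s2, "prenatal", registry = reg)
  expect_equal(b$log2_value, a$log2_value + 1, tolerance = 1e-12)
})
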