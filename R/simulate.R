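#' Specify a synthetic cohort
#'
#' Builds the parameter object consumed by [simulate_cohort()]. Defaults are
#' calibrated to the pooled-cohort setting the package targets: right-skewed
#' (lognormal) exposure distributions summarised by geometric means and
#' geometric standard deviations, repeated binary allergy outcomes with
#' realistic prevalences, a moderate within-subject dependence induced by a
#' shared lognormal frailty, and covariate marginals typical of
#' birth-cohort studies.
#'
#' Exposure effects are specified on the per-doubling scale: for analyte a
#' and outcome o, `true_rr[[o]][a]` multiplies the outcome risk for each
#' doubling of the analyte (log-link risk model). `true_rr` entries default
#' to 1 (no effect).
#'
#' @param cohort_id Cohort label.
#' @param n_subjects Number of subjects.
#' @param period `"prenatal"` or `"postnatal"`.
#' @param exposure_gm Named vector of geometric means (ug/L or ug/kg/day).
#' @param exposure_gsd Named vector of geometric standard deviations (> 1).
#' @param log_correlation Correlation matrix of log exposures across
#'   analytes (unit diagonal, positive semi-definite). Default: exchangeable
#'   with correlation 0.3, a typical magnitude for co-excreted metabolites.
#' @param lod Named vector of limits of detection on the concentration
#'   scale; `NULL` for no censoring.
#' @param sampling_times Urine sampling times: gestational weeks (prenatal)
#'   or child ages in years (postnatal).
#' @param assessment_ages Child ages (years) at outcome assessments.
#' @param outcome_baseline Named vector of per-assessment baseline risks.
#' @param true_rr Named list: per outcome, a named vector of per-doubling
#'   risk ratios over analytes.
#' @param mixture_rr Named list: per outcome, the joint per-quantile risk
#'   ratio of the whole mixture. The effect is split equally across
#'   analytes and applied to population-quantile scores (cut points of the
#'   marginal lognormal), centred so the baseline prevalence is preserved.
#' @param mixture_q Number of quantiles defining the mixture scores.
#' @param subject_icc Share of log-exposure variance at the subject level
#'   (within-subject reproducibility of repeated urine samples).
#' @param frailty_sd Standard deviation of the shared log-frailty that
#'   induces within-subject outcome dependence.
#' @param covariates Covariate distribution list; see
#'   [default_covariate_spec()].
#' @param missingness Named vector of missing-completely-at-random rates for
#'   covariate columns.
#' @param confounding Optional list (`covariate`, `exposure_log2_shift`,
#'   `rr`) making a binary covariate shift both exposure and outcome risk,
#'   to exercise confounder adjustment and selection-bias corrections.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort_id = "SYN",
                        n_subjects = 1000,
                        period = c("prenatal", "postnatal"),
                        exposure_gm = c(DEHP = 3.85),
                        exposure_gsd = c(DEHP = 3.78),
                        log_correlation = NULL,
                        lod = NULL,
                        sampling_times = NULL,
                        assessment_ages = NULL,
                        outcome_baseline = c(asthma = 0.146),
                        true_rr = list(),
                        mixture_rr = list(),
                        mixture_q = 4,
                        subject_icc = 0.6,
                        frailty_sd = 0.3,
                        covariates = default_covariate_spec(match.arg(period)),
                        missingness = c(),
                        confounding = NULL) {
  period <- match.arg(period)
  analytes <- names(exposure_gm)
  stopifnot(length(analytes) > 0, !is.null(analytes),
            setequal(analytes, names(exposure_gsd)))
  exposure_gsd <- exposure_gsd[analytes]
  if (any(exposure_gsd <= 1)) stop("exposure_gsd must exceed 1")
  stopifnot(all(outcome_baseline > 0), all(outcome_baseline < 1))
  if (any(missingness < 0) || any(missingness >= 1)) {
    stop("missingness rates must lie in [0, 1)")
  }
  k <- length(analytes)
  if (is.null(log_correlation)) {
    log_correlation <- matrix(0.3, k, k)
    diag(log_correlation) <- 1
    dimnames(log_correlation) <- list(analytes, analytes)
  }
  stopifnot(nrow(log_correlation) == k, ncol(log_correlation) == k)
  if (max(abs(log_correlation - t(log_correlation))) > 1e-8 ||
      max(abs(diag(log_correlation) - 1)) > 1e-8) {
    stop("log_correlation must be symmetric with unit diagonal")
  }
  ev <- eigen(log_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("log_correlation is not positive semi-definite")
  if (is.null(sampling_times)) {
    sampling_times <- if (period == "prenatal") c(16, 26, 36) else c(1, 2, 3)
  }
  if (is.null(assessment_ages)) {
    assessment_ages <- if (period == "prenatal") c(1, 2, 4) else
      sampling_times + 0.5 * c(diff(sampling_times), 2)
  }
  structure(
    list(cohort_id = cohort_id, n_subjects = n_subjects, period = period,
         analytes = analytes, exposure_gm = exposure_gm,
         exposure_gsd = exposure_gsd, log_correlation = log_correlation,
         lod = lod, sampling_times = sampling_times,
         assessment_ages = assessment_ages,
         outcome_baseline = outcome_baseline, true_rr = true_rr,
         mixture_rr = mixture_rr, mixture_q = mixture_q,
         subject_icc = subject_icc, frailty_sd = frailty_sd,
         covariates = covariates, missingness = missingness,
         confounding = confounding),
    class = "cohort_spec")
}

#' Default covariate distributions for the synthetic generator
#'
#' Marginals match the pooled descriptive statistics of the target setting:
#' categorical frequencies for sex, ethnicity, marital status, caregiver
#' education, family history of asthma, season of birth and smoke exposure,
#' and normal distributions for maternal age and (postnatally)
#' breastfeeding duration and gestational age.
#'
#' @param period `"prenatal"` or `"postnatal"`.
#' @return A named list of distribution descriptors.
#' @export
default_covariate_spec <- function(period = c("prenatal", "postnatal")) {
  period <- match.arg(period)
  if (period == "prenatal") {
    list(
      sex = list(type = "categorical", levels = c("male", "female"),
                 p = c(0.509, 0.491)),
      maternal_age = list(type = "normal", mean = 30.4, sd = 5.6),
      ethnicity = list(type = "categorical", levels = c("white", "other"),
                       p = c(0.597, 0.403)),
      marital_status = list(type = "categorical",
                            levels = c("other", "single"), p = c(0.807, 0.193)),
      education = list(type = "categorical",
                       levels = c("high_school", "bachelor", "postgraduate", "other"),
                       p = c(0.218, 0.297, 0.248, 0.237)),
      family_history_asthma = list(type = "categorical",
                                   levels = c("no", "yes"), p = c(0.605, 0.395)),
      season_of_birth = list(type = "categorical",
                             levels = c("spring", "summer", "autumn", "winter"),
                             p = c(0.248, 0.240, 0.246, 0.266)),
      prenatal_smoke = list(type = "categorical", levels = c("no", "yes"),
                            p = c(0.855, 0.145))
    )
  } else {
    list(
      sex = list(type = "categorical", levels = c("male", "female"),
                 p = c(0.521, 0.479)),
      maternal_age = list(type = "normal", mean = 31.8, sd = 4.9),
      ethnicity = list(type = "categorical", levels = c("white", "other"),
                       p = c(0.703, 0.297)),
      marital_status = list(type = "categorical",
                            levels = c("other", "single"), p = c(0.922, 0.078)),
      education = list(type = "categorical",
                       levels = c("high_school", "bachelor", "postgraduate", "other"),
                       p = c(0.064, 0.513, 0.285, 0.138)),
      family_history_asthma = list(type = "categorical",
                                   levels = c("no", "yes"), p = c(0.772, 0.228)),
      season_of_birth = list(type = "categorical",
                             levels = c("spring", "summer", "autumn", "winter"),
                             p = c(0.288, 0.303, 0.202, 0.207)),
      prenatal_smoke = list(type = "categorical", levels = c("no", "yes"),
                            p = c(0.726, 0.274)),
      breastfeeding_weeks = list(type = "normal", mean = 39.6, sd = 27.6,
                                 lower = 0),
      gestational_age = list(type = "normal", mean = 39.1, sd = 1.5),
      postnatal_smoke = list(type = "categorical", levels = c("no", "yes"),
                             p = c(0.651, 0.349))
    )
  }
}

#' Draw multivariate lognormal exposure samples
#'
#' Per-analyte concentrations are multivariate lognormal with the requested
#' geometric means, geometric standard deviations and log-scale correlation.
#' Repeated samples of the same subject share a subject-level random
#' component whose variance share is `subject_icc`; the visit-level
#' component carries the remaining variance with the same correlation
#' structure, so the marginal distribution matches the spec at every visit.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of urine samples (one row per subject, sampling time and
#'   analyte) with columns `subject_id`, `cohort_id`, `sampling_time`,
#'   `analyte`, `concentration`, plus dilution/batch/clock metadata.
#' @export
sim_exposures <- function(spec) {
  n <- spec$n_subjects
  k <- length(spec$analytes)
  tt <- spec$sampling_times
  m <- length(tt)
  mu <- log(spec$exposure_gm)
  sigma <- log(spec$exposure_gsd)
  L <- chol_psd(spec$log_correlation)
  draw <- function(nr) matrix(stats::rnorm(nr * k), nr, k) %*% L
  z_subj <- draw(n) * sqrt(spec$subject_icc)
  logx <- matrix(NA_real_, n * m, k)
  for (j in seq_len(m)) {
    z <- z_subj + draw(n) * sqrt(1 - spec$subject_icc)
    logx[(j - 1) * n + seq_len(n), ] <-
      sweep(sweep(z, 2, sigma, `*`), 2, mu, `+`)
  }
  subj <- sprintf("%s_%04d", spec$cohort_id, seq_len(n))
  base <- tibble::tibble(
    subject_id = rep(rep(subj, times = m), each = 1),
    cohort_id = spec$cohort_id,
    sampling_time = rep(tt, each = n)
  )
  conc <- exp(logx)
  colnames(conc) <- spec$analytes
  out <- dplyr::bind_cols(base, tibble::as_tibble(conc))
  out <- tidyr::pivot_longer(out, dplyr::all_of(spec$analytes),
                             names_to = "analyte", values_to = "concentration")
  nsamp <- nrow(base)
  meta <- tibble::tibble(
    subject_id = base$subject_id, sampling_time = base$sampling_time,
    specific_gravity = pmin(1.05, 1.001 + stats::rgamma(nsamp, shape = 9, scale = 0.0017)),
    creatinine = stats::rlnorm(nsamp, log(95), 0.5),
    batch = sample(paste0("B", 1:4), nsamp, replace = TRUE),
    clock_time = stats::runif(nsamp, 7, 20)
  )
  dplyr::left_join(out, meta, by = c("subject_id", "sampling_time"))
}

# Cholesky factor tolerant of semi-definite matrices.
chol_psd <- function(R) {
  ch <- try(chol(R), silent = TRUE)
  if (!inherits(ch, "try-error")) return(ch)
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("correlation matrix is not positive semi-definite")
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(R)))
}

#' Censor sample concentrations at the limit of detection
#'
#' Values strictly below the analyte's LOD are flagged `censored` and the
#' reported concentration is withheld (`NA`); detected values are preserved.
#'
#' @param samples Urine-sample tibble with `analyte` and `concentration`.
#' @param lod Named vector of LODs (ug/L); analytes without an entry are
#'   left uncensored.
#' @return The samples with `lod` and `censored` columns and masked
#'   below-LOD concentrations.
#' @export
sim_censor_lod <- function(samples, lod) {
  if (is.null(lod) || length(lod) == 0) lod <- numeric(0)
  stopifnot(all(lod >= 0))
  lv <- unname(lod[samples$analyte])
  lv[is.na(lv)] <- 0
  samples$lod <- lv
  samples$censored <- samples$concentration < lv
  samples$concentration <- ifelse(samples$censored, NA_real_,
                                  samples$concentration)
  tibble::as_tibble(samples)
}

#' Simulate repeated binary outcomes under a log-link risk model
#'
#' Per-assessment risk for outcome o is
#' `baseline_o * prod_a rr[a]^(log2 x_a - log2 gm_a) * u`, where `x_a` is
#' the subject's analysis-scale exposure (prenatal: subject average over
#' sampling times; postnatal: the most recent sample before the
#' assessment), and `u` is a subject-level lognormal frailty with mean 1
#' inducing exchangeable-type within-subject dependence. Risks above 0.99
#' are truncated with a warning.
#'
#' @param spec A [cohort_spec()].
#' @param samples Exposure samples from [sim_exposures()].
#' @param covariates Optional covariate table (needed when `spec$confounding`
#'   is set).
#' @return A tibble of outcome records: `subject_id`, `outcome`,
#'   `age_at_assessment`, `status`.
#' @export
sim_outcomes <- function(spec, samples, covariates = NULL) {
  wide <- tidyr::pivot_wider(
    samples[, c("subject_id", "sampling_time", "analyte", "concentration")],
    names_from = "analyte", values_from = "concentration")
  subj <- unique(wide$subject_id)
  n <- length(subj)
  u <- stats::rlnorm(n, -spec$frailty_sd^2 / 2, spec$frailty_sd)
  names(u) <- subj
  conf_mult <- rep(1, n)
  names(conf_mult) <- subj
  if (!is.null(spec$confounding) && !is.null(covariates)) {
    cv <- spec$confounding
    flag <- covariates[[cv$covariate]][match(subj, covariates$subject_id)]
    conf_mult <- ifelse(flag == cv$level, cv$rr, 1)
    names(conf_mult) <- subj
  }
  rows <- list()
  trunc_count <- 0L
  for (oc in names(spec$outcome_baseline)) {
    rr <- spec$true_rr[[oc]]
    for (age in spec$assessment_ages) {
      if (spec$period == "prenatal") {
        x <- stats::aggregate(wide[spec$analytes],
                              by = list(subject_id = wide$subject_id), mean)
      } else {
        prior <- spec$sampling_times[spec$sampling_times < age]
        t_use <- if (length(prior)) max(prior) else min(spec$sampling_times)
        x <- wide[wide$sampling_time == t_use, c("subject_id", spec$analytes)]
      }
      lp <- rep(0, nrow(x))
      if (!is.null(rr)) {
        for (a in intersect(names(rr), spec$analytes)) {
          lp <- lp + log(rr[[a]]) *
            (log2(x[[a]]) - log2(spec$exposure_gm[[a]]))
        }
      }
      mix <- spec$mixture_rr[[oc]]
      if (!is.null(mix)) {
        qm <- spec$mixture_q
        b <- log(mix) / length(spec$analytes)
        for (a in spec$analytes) {
          cuts <- stats::qlnorm(seq_len(qm - 1) / qm,
                                log(spec$exposure_gm[[a]]),
                                log(spec$exposure_gsd[[a]]))
          score <- findInterval(x[[a]], cuts)
          lp <- lp + b * (score - (qm - 1) / 2)
        }
      }
      p <- spec$outcome_baseline[[oc]] * exp(lp) *
        u[x$subject_id] * conf_mult[x$subject_id]
      trunc_count <- trunc_count + sum(p > 0.99)
      p <- pmin(p, 0.99)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = x$subject_id, outcome = oc, age_at_assessment = age,
        status = stats::rbinom(nrow(x), 1, p) == 1
      )
    }
  }
  if (trunc_count > 0) {
    warning(trunc_count, " simulated risks exceeded 0.99 and were truncated")
  }
  dplyr::bind_rows(rows)
}

#' Simulate subject covariates with MCAR missingness
#'
#' Covariates are drawn independently from the marginals in
#' `spec$covariates`; entries are then masked completely at random at the
#' per-column rates in `spec$missingness`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject.
#' @export
sim_covariates <- function(spec) {
  n <- spec$n_subjects
  subj <- sprintf("%s_%04d", spec$cohort_id, seq_len(n))
  cols <- purrr::imap(spec$covariates, function(d, nm) {
    if (d$type == "categorical") {
      factor(sample(d$levels, n, replace = TRUE, prob = d$p), levels = d$levels)
    } else {
      v <- stats::rnorm(n, d$mean, d$sd)
      if (!is.null(d$lower)) v <- pmax(v, d$lower)
      v
    }
  })
  out <- tibble::as_tibble(cols)
  out <- dplyr::bind_cols(tibble::tibble(subject_id = subj), out)
  for (nm in names(spec$missingness)) {
    if (!nm %in% names(out)) next
    mask <- stats::runif(n) < spec$missingness[[nm]]
    out[[nm]][mask] <- NA
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Runs the exposure, censoring, covariate and outcome generators under one
#' seed and returns the combined study object. Identical `spec` and `seed`
#' give byte-identical output.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return An object of class `simulated_study`: a list with tibbles
#'   `urine_samples`, `outcomes`, `covariates` and the generating `truth`.
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  set.seed(seed)
  samples <- sim_exposures(spec)
  covariates <- sim_covariates(spec)
  if (!is.null(spec$confounding)) {
    cv <- spec$confounding
    flag <- covariates[[cv$covariate]][match(samples$subject_id,
                                             covariates$subject_id)]
    samples$concentration <- samples$concentration *
      2^(ifelse(flag == cv$level, cv$exposure_log2_shift, 0))
  }
  outcomes <- sim_outcomes(spec, samples, covariates)
  samples <- sim_censor_lod(samples, spec$lod)
  structure(list(urine_samples = samples, outcomes = outcomes,
                 covariates = covariates, truth = spec),
            class = "simulated_study")
}

#' Convert simulated urine samples to analysis-scale exposure records
#'
#' The generator draws concentrations directly on the analysis scale
#' (EDI in ug/kg/day, or ug/L for concentration-scale analytes), so for
#' simulation studies of the modelling stages the samples map one-to-one to
#' exposure records without the standardization/intake chain.
#'
#' @param study A `simulated_study` (or its `urine_samples` tibble).
#' @param scale `"edi"` or `"concentration"` label for the records.
#' @return Exposure records as produced by [derive_exposures()].
#' @export
sim_exposure_records <- function(study, scale = "edi") {
  samples <- if (inherits(study, "simulated_study")) study$urine_samples else study
  period <- if (inherits(study, "simulated_study")) study$truth$period else "prenatal"
  out <- tibble::tibble(
    subject_id = samples$subject_id, cohort_id = samples$cohort_id,
    parent_code = samples$analyte, period = period,
    timing = samples$sampling_time, value = samples$concentration,
    scale = scale, log2_value = log2(samples$concentration))
  out[!is.na(out$value), ]
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study> cohort", x$truth$cohort_id,
      "|", x$truth$n_subjects, "subjects |", x$truth$period, "period\n")
  cat("  analytes:", paste(x$truth$analytes, collapse = ", "), "\n")
  cat("  samples:", nrow(x$urine_samples), "rows; outcomes:",
      nrow(x$outcomes), "rows\n")
  invisible(x)
}
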