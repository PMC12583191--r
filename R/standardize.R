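#' Correct urinary concentrations for dilution
#'
#' Applies the specific-gravity (Levine-Fahey) or creatinine (Boeniger)
#' correction: with observed analyte E0 and observed dilution measure Sg0 or
#' Cr0,
#' \deqn{E_{sg} = E_0 \times (Sg_{median} - 1) / (Sg_0 - 1)}
#' \deqn{E_{cr} = E_0 \times Cr_{median} / Cr_0}
#' The medians are taken over the study sample being standardized (or
#' supplied explicitly). Censored rows (no reported concentration) pass
#' through untouched: below-LOD handling operates on the raw assay scale and
#' precedes dilution correction in [standardize_urine()].
#'
#' @param samples Urine-sample tibble with `concentration` and, depending on
#'   `method`, `specific_gravity` or `creatinine`.
#' @param method `"specific_gravity"` or `"creatinine"`.
#' @param reference_median Median of the dilution variable in the study
#'   sample; computed from `samples` when `NULL`.
#' @return `samples` with `concentration` replaced by the corrected value
#'   and the reference median recorded in the `dilution_reference` column.
#' @export
standardize_dilution <- function(samples,
                                 method = c("specific_gravity", "creatinine"),
                                 reference_median = NULL) {
  method <- match.arg(method)
  var <- samples[[method]]
  obs <- !is.na(samples$concentration)
  if (any(obs & is.na(var))) {
    stop("dilution variable '", method, "' missing for ",
         sum(obs & is.na(var)), " uncensored samples")
  }
  if (method == "specific_gravity") {
    bad <- obs & var <= 1
    if (any(bad, na.rm = TRUE)) {
      stop("specific gravity <= 1 for sample(s) ",
           paste(utils::head(which(bad), 3), collapse = ", "),
           ": dilution factor degenerate")
    }
    if (is.null(reference_median)) reference_median <- stats::median(var, na.rm = TRUE)
    factor <- (reference_median - 1) / (var - 1)
  } else {
    bad <- obs & var <= 0
    if (any(bad, na.rm = TRUE)) {
      stop("creatinine <= 0 for sample(s) ",
           paste(utils::head(which(bad), 3), collapse = ", "),
           ": dilution factor degenerate")
    }
    if (is.null(reference_median)) reference_median <- stats::median(var, na.rm = TRUE)
    factor <- reference_median / var
  }
  samples$concentration <- ifelse(obs, samples$concentration * factor,
                                  samples$concentration)
  samples$dilution_reference <- reference_median
  tibble::as_tibble(samples)
}

#' Handle below-LOD measurements
#'
#' Two strategies for left-censored measurements:
#' * `"sqrt2"` — each censored value is replaced by LOD/sqrt(2), the
#'   standard substitution for moderately censored phthalates;
#' * `"censored_lognormal_mi"` — per analyte, a lognormal distribution is
#'   fitted by maximum likelihood treating censored observations through the
#'   left-censored likelihood, and each censored value is drawn from the
#'   fitted lognormal truncated to (0, LOD), independently in each of `m`
#'   imputations (used for bisphenols, whose detection rates are lower).
#'
#' Detected values are never altered under either method.
#'
#' @param samples Urine-sample tibble with `analyte`, `concentration`,
#'   `censored`, `lod`.
#' @param method `"sqrt2"` or `"censored_lognormal_mi"`.
#' @param m Number of imputations (MI method).
#' @param seed Integer seed for the MI draws.
#' @return For `"sqrt2"`, the completed tibble. For the MI method, a tibble
#'   stacking `m` completed copies distinguished by an `.imp` column.
#' @export
handle_lod <- function(samples, method = c("sqrt2", "censored_lognormal_mi"),
                       m = 5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(all(c("analyte", "concentration", "censored", "lod") %in% names(samples)))
  cens <- samples$censored
  if (any(cens & (is.na(samples$lod) | samples$lod <= 0))) {
    stop("every censored sample must carry a positive LOD")
  }
  if (method == "sqrt2") {
    samples$concentration <- ifelse(cens, samples$lod / sqrt(2),
                                    samples$concentration)
    return(tibble::as_tibble(samples))
  }
  if (!any(cens)) {
    out <- dplyr::bind_rows(purrr::map(seq_len(m), function(i) {
      dplyr::mutate(samples, .imp = i)
    }))
    return(tibble::as_tibble(out))
  }
  fits <- list()
  for (a in unique(samples$analyte[cens])) {
    idx <- samples$analyte == a
    if (all(samples$censored[idx])) {
      stop("analyte '", a, "' is censored in every sample; the censored ",
           "likelihood cannot be fitted - exclude this analyte")
    }
    fits[[a]] <- fit_censored_lognormal(
      values = samples$concentration[idx],
      censored = samples$censored[idx],
      lod = samples$lod[idx])
  }
  out <- purrr::map(seq_len(m), function(i) {
    set.seed(seed + i)
    imp <- samples
    for (a in names(fits)) {
      sel <- which(imp$analyte == a & imp$censored)
      f <- fits[[a]]
      # inverse-CDF draw from lognormal truncated to (0, LOD)
      p_lod <- stats::plnorm(imp$lod[sel], f$meanlog, f$sdlog)
      imp$concentration[sel] <- stats::qlnorm(stats::runif(length(sel)) * p_lod,
                                              f$meanlog, f$sdlog)
    }
    imp$.imp <- i
    imp
  })
  tibble::as_tibble(dplyr::bind_rows(out))
}

#' Fit a left-censored lognormal by maximum likelihood
#'
#' @param values Observed concentrations (`NA` where censored).
#' @param censored Logical censoring flags.
#' @param lod LODs (used for censored rows).
#' @return A list with `meanlog` and `sdlog`.
#' @export
fit_censored_lognormal <- function(values, censored, lod) {
  d <- data.frame(
    left = ifelse(censored, NA_real_, values),
    right = ifelse(censored, lod, values)
  )
  f <- fitdistrplus::fitdistcens(d, "lnorm")
  list(meanlog = unname(f$estimate["meanlog"]),
       sdlog = unname(f$estimate["sdlog"]))
}

#' Adjust log concentrations for time of day at sampling
#'
#' The residual method: log concentration is regressed on linear and
#' quadratic clock-time terms and replaced by the residual plus the grand
#' mean, removing the diurnal trend while preserving the mean.
#'
#' @param log_values Log-scale concentrations.
#' @param clock_time Sampling clock time in hours (0-24).
#' @return Adjusted log concentrations.
#' @export
residual_time_adjust <- function(log_values, clock_time) {
  stopifnot(length(log_values) == length(clock_time))
  if (anyNA(clock_time)) stop("clock time must be present for all samples")
  if (length(unique(clock_time)) < 3) {
    warning("clock time (nearly) constant; time-of-day adjustment is a no-op")
    return(log_values)
  }
  fit <- stats::lm(log_values ~ clock_time + I(clock_time^2))
  unname(stats::residuals(fit) + mean(log_values))
}

#' Equalize batch means on the log scale
#'
#' Analytical batch differences are removed by centering each batch at the
#' grand mean of the log concentrations; the between-batch variance of
#' means is zero afterwards and the overall mean is preserved. Singleton
#' batches are left unadjusted with a warning.
#'
#' @param log_values Log-scale concentrations.
#' @param batch Batch labels.
#' @return Adjusted log concentrations.
#' @export
batch_adjust <- function(log_values, batch) {
  stopifnot(length(log_values) == length(batch))
  batch <- as.character(batch)
  sizes <- table(batch)
  single <- names(sizes)[sizes < 2]
  if (length(single) > 0) {
    warning("singleton batch(es) left unadjusted: ",
            paste(single, collapse = ", "))
  }
  grand <- mean(log_values)
  means <- tapply(log_values, batch, mean)
  shift <- as.vector(grand - means[batch])
  shift[batch %in% single] <- 0
  unname(log_values + shift)
}

#' Impute missing dilution measurements by linear regression
#'
#' Missing specific-gravity (or creatinine) values are predicted from a
#' linear regression on the supplied predictors, fitted to the complete
#' rows; observed values are untouched. Specific-gravity predictions are
#' floored just above 1 so the Levine-Fahey denominator stays positive.
#'
#' @param samples Tibble containing the dilution column and predictor
#'   columns.
#' @param dilution_var Name of the dilution column.
#' @param predictors Character vector of predictor column names (e.g.
#'   gestational age at sampling, maternal age, pre-pregnancy weight).
#' @param floor Lower bound applied to predictions (default 1.001 for
#'   specific gravity; use 0 for creatinine).
#' @return `samples` with the dilution column completed.
#' @export
impute_missing_dilution <- function(samples, dilution_var = "specific_gravity",
                                    predictors, floor = 1.001) {
  y <- samples[[dilution_var]]
  miss <- is.na(y)
  if (!any(miss)) return(tibble::as_tibble(samples))
  complete <- stats::complete.cases(samples[, c(dilution_var, predictors)])
  if (sum(complete) < 30) {
    stop("need at least 30 complete rows to fit the dilution imputation model")
  }
  form <- stats::reformulate(predictors, response = dilution_var)
  fit <- stats::lm(form, data = samples[complete, , drop = FALSE])
  pred <- stats::predict(fit, newdata = samples[miss, , drop = FALSE])
  samples[[dilution_var]][miss] <- pmax(pred, floor)
  tibble::as_tibble(samples)
}

#' Run the full concentration standardization chain
#'
#' Order of operations: below-LOD handling on the raw assay scale, then
#' dilution correction, then (optionally) time-of-day and batch adjustment
#' on the log scale per analyte. The time and batch stages are skippable to
#' mirror assay profiles in which those corrections were not applied.
#'
#' @param samples Urine-sample tibble (one analyte measurement per row).
#' @param dilution_method `"specific_gravity"` or `"creatinine"`.
#' @param lod_method Passed to [handle_lod()].
#' @param adjust_time,adjust_batch Logical switches for the log-scale
#'   stages.
#' @param m,seed MI settings for [handle_lod()].
#' @return A tibble with standardized concentrations (stacked over `.imp`
#'   when multiple imputation is used).
#' @export
standardize_urine <- function(samples,
                              dilution_method = c("specific_gravity", "creatinine"),
                              lod_method = c("sqrt2", "censored_lognormal_mi"),
                              adjust_time = FALSE, adjust_batch = FALSE,
                              m = 5, seed = 1L) {
  dilution_method <- match.arg(dilution_method)
  lod_method <- match.arg(lod_method)
  filled <- handle_lod(samples, method = lod_method, m = m, seed = seed)
  if (!".imp" %in% names(filled)) filled$.imp <- 1L
  out <- filled |>
    dplyr::group_by(.data$.imp) |>
    dplyr::group_modify(function(d, key) {
      d <- standardize_dilution(d, method = dilution_method)
      d <- d |>
        dplyr::group_by(.data$analyte) |>
        dplyr::group_modify(function(g, k2) {
          lv <- log(g$concentration)
          if (adjust_time) lv <- residual_time_adjust(lv, g$clock_time)
          if (adjust_batch) lv <- batch_adjust(lv, g$batch)
          g$concentration <- exp(lv)
          g
        }) |>
        dplyr::ungroup()
      d
    }) |>
    dplyr::ungroup()
  if (max(out$.imp) == 1L && !".imp" %in% names(samples)) out$.imp <- NULL
  tibble::as_tibble(out)
}
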