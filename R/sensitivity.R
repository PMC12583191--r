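#' E-value for unmeasured confounding
#'
#' The E-value is the minimum strength of association, on the risk-ratio
#' scale, that an unmeasured confounder would need with both the exposure
#' and the outcome to fully explain an observed association. For RR >= 1,
#' `E = RR + sqrt(RR * (RR - 1))`; protective estimates are inverted first.
#' The CI-bound E-value applies the same formula to the confidence limit
#' closer to the null and is 1 when the interval crosses 1.
#'
#' @param rr Observed risk ratio (> 0).
#' @param ci_low,ci_high Optional 95% confidence limits.
#' @return A tibble with `rr`, `evalue_point` and (when a CI is supplied)
#'   `evalue_ci`.
#' @export
#' @examples
#' evalue(1.08)   # 1.37
#' evalue(1.14)   # 1.54
evalue <- function(rr, ci_low = NULL, ci_high = NULL) {
  if (any(rr <= 0)) stop("risk ratio must be positive")
  epoint <- function(r) {
    r <- ifelse(r < 1, 1 / r, r)
    r + sqrt(r * (r - 1))
  }
  out <- tibble::tibble(rr = rr, evalue_point = epoint(rr))
  if (!is.null(ci_low) && !is.null(ci_high)) {
    crosses <- ci_low <= 1 & ci_high >= 1
    near <- ifelse(rr >= 1, ci_low, ci_high)
    out$evalue_ci <- ifelse(crosses, 1, epoint(near))
  }
  out
}

#' Random-effects meta-analysis of cohort-stratified estimates
#'
#' Pools per-cohort log risk ratios under a random-effects model with the
#' between-cohort variance tau^2 estimated by restricted maximum
#' likelihood; the pooled estimate is the inverse-variance weighted mean
#' with weights 1/(se_i^2 + tau^2). Heterogeneity is summarised by I^2 from
#' Cochran's Q, `max(0, (Q - df)/Q) * 100`. A single cohort passes through
#' unchanged with tau^2 = 0.
#'
#' @param estimates Tibble with columns `cohort_id`, `log_rr` and `se`
#'   (log-scale standard errors, > 0).
#' @return An object of class `meta_fit`: tibble-like list with
#'   `pooled_rr`, `ci_low`, `ci_high`, `tau2`, `i2`, and the per-cohort
#'   input.
#' @export
random_effects_meta <- function(estimates) {
  stopifnot(all(c("cohort_id", "log_rr", "se") %in% names(estimates)))
  if (any(estimates$se <= 0)) stop("standard errors must be positive")
  k <- nrow(estimates)
  if (k == 1) {
    res <- list(pooled_log_rr = estimates$log_rr, pooled_se = estimates$se,
                tau2 = 0, i2 = 0, q = 0)
  } else {
    fit <- metafor::rma(yi = estimates$log_rr, sei = estimates$se,
                        method = "REML")
    q <- as.numeric(fit$QE)
    res <- list(pooled_log_rr = as.numeric(fit$beta), pooled_se = fit$se,
                tau2 = fit$tau2, i2 = max(0, (q - (k - 1)) / q) * 100, q = q)
  }
  structure(
    list(pooled_rr = exp(res$pooled_log_rr),
         ci_low = exp(res$pooled_log_rr - 1.96 * res$pooled_se),
         ci_high = exp(res$pooled_log_rr + 1.96 * res$pooled_se),
         pooled_log_rr = res$pooled_log_rr, pooled_se = res$pooled_se,
         tau2 = res$tau2, i2 = res$i2, q = res$q, k = k,
         per_cohort = tibble::as_tibble(estimates)),
    class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("Random-effects meta-analysis (REML),", x$k, "cohorts\n")
  cat(sprintf("  pooled RR %.3f (%.3f-%.3f); tau2 = %.4f; I2 = %.1f%%\n",
              x$pooled_rr, x$ci_low, x$ci_high, x$tau2, x$i2))
  invisible(x)
}

#' Stabilized inverse-probability-of-selection weights
#'
#' Corrects for differential inclusion from an inception cohort into the
#' analysis sample: inclusion is modelled by logistic regression on the
#' supplied covariates; included subjects receive weight
#' `P(included) / P(included | covariates)`. Weights are truncated at their
#' 1st and 99th percentiles by default (switchable) to control variance;
#' stabilization makes their mean approximately 1.
#'
#' @param inception Per-subject table covering the inception sample.
#' @param inclusion Name of the logical/0-1 inclusion column.
#' @param covariate_formula One-sided formula of selection covariates.
#' @param truncate Quantile pair for truncation, or `NULL` to disable.
#' @return A tibble of included subjects with their `ipw` weight.
#' @export
stabilized_ipw <- function(inception, inclusion = "included",
                           covariate_formula, truncate = c(0.01, 0.99)) {
  s <- as.integer(inception[[inclusion]])
  stopifnot(all(s %in% 0:1))
  f <- stats::update(covariate_formula, paste(inclusion, "~ ."))
  fit <- suppressWarnings(stats::glm(f, data = inception,
                                     family = stats::binomial()))
  phat <- stats::fitted(fit)
  if (!fit$converged || any(phat < 1e-6) || any(phat > 1 - 1e-6)) {
    stop("covariates perfectly predict inclusion for some subjects; ",
         "selection weights are not identifiable")
  }
  w <- mean(s) / phat
  out <- inception[s == 1, , drop = FALSE]
  w <- w[s == 1]
  if (!is.null(truncate)) {
    bounds <- stats::quantile(w, truncate)
    w <- pmin(pmax(w, bounds[1]), bounds[2])
  }
  out$ipw <- unname(w)
  tibble::as_tibble(out)
}

#' Multiple imputation of covariates by chained equations
#'
#' Fills missing covariate entries by iterating per-variable conditional
#' models over the incomplete columns: Bayesian linear regression for
#' continuous variables (coefficients and residual variance drawn from
#' their posterior), logistic regression for two-level factors, and a
#' multinomial model for factors with more levels (draws from the fitted
#' class probabilities). Starting values are sampled from the observed
#' margins. Variables missing entirely raise an error; variables more than
#' half missing raise a warning.
#'
#' @param data A data frame; only columns with missing values are imputed,
#'   using all other columns as predictors.
#' @param m Number of imputed datasets.
#' @param iterations Chained-equation sweeps per dataset.
#' @param seed Integer seed.
#' @param exclude Columns never used as predictors or imputed (ids).
#' @return A tibble stacking the `m` completed datasets with an `.imp`
#'   column.
#' @export
impute_covariates <- function(data, m = 5, iterations = 20, seed = 1L,
                              exclude = "subject_id") {
  vars <- setdiff(names(data), exclude)
  miss <- vars[purrr::map_lgl(vars, ~ anyNA(data[[.x]]))]
  for (v in miss) {
    fr <- mean(is.na(data[[v]]))
    if (fr == 1) stop("variable '", v, "' has no observed values")
    if (fr > 0.5) warning("variable '", v, "' is more than 50% missing")
  }
  if (length(miss) == 0) {
    out <- dplyr::bind_rows(purrr::map(seq_len(m), ~ dplyr::mutate(data, .imp = .x)))
    return(tibble::as_tibble(out))
  }
  preds <- setdiff(vars, character(0))
  set.seed(seed)
  completed <- purrr::map(seq_len(m), function(i) {
    d <- data
    for (v in miss) {                       # initial fill from observed margin
      na_idx <- which(is.na(d[[v]]))
      d[[v]][na_idx] <- sample(stats::na.omit(data[[v]]), length(na_idx),
                               replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in miss) {
        na_idx <- which(is.na(data[[v]]))
        rhs <- setdiff(preds, v)
        f <- stats::reformulate(rhs, response = v)
        d[[v]] <- impute_one(d, f, v, na_idx, observed = data[[v]])
      }
    }
    dplyr::mutate(d, .imp = i)
  })
  tibble::as_tibble(dplyr::bind_rows(completed))
}

# One conditional-model draw for the chained-equation sweep.
impute_one <- function(d, formula, v, na_idx, observed) {
  y <- d[[v]]
  obs_idx <- setdiff(seq_len(nrow(d)), na_idx)
  if (is.numeric(y)) {
    fit <- stats::lm(formula, data = d[obs_idx, , drop = FALSE])
    Xn <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                              d[na_idx, , drop = FALSE])
    df <- fit$df.residual
    sigma2 <- sum(stats::residuals(fit)^2) / stats::rchisq(1, df)
    Vb <- sigma2 * chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
    bstar <- stats::coef(fit) +
      drop(t(chol(Vb)) %*% stats::rnorm(length(stats::coef(fit))))
    y[na_idx] <- drop(Xn %*% bstar) + stats::rnorm(length(na_idx), 0, sqrt(sigma2))
  } else {
    lv <- levels(as.factor(observed))
    if (length(lv) == 2) {
      fit <- stats::glm(formula, data = d[obs_idx, , drop = FALSE],
                        family = stats::binomial())
      p <- stats::predict(fit, newdata = d[na_idx, , drop = FALSE],
                          type = "response")
      y[na_idx] <- factor(lv[1 + stats::rbinom(length(na_idx), 1, p)], levels = lv)
    } else {
      fit <- nnet::multinom(formula, data = d[obs_idx, , drop = FALSE],
                            trace = FALSE)
      p <- stats::predict(fit, newdata = d[na_idx, , drop = FALSE],
                          type = "probs")
      if (is.null(dim(p))) p <- matrix(p, nrow = 1)
      draw <- apply(p, 1, function(pr) sample(colnames(p), 1, prob = pr))
      y[na_idx] <- factor(draw, levels = lv)
    }
  }
  y
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' @param estimates Per-imputation point estimates (log scale).
#' @param variances Per-imputation squared standard errors.
#' @return A tibble with the pooled estimate, within/between/total
#'   variance, pooled SE and 95% CI (normal reference when the Rubin
#'   degrees of freedom are large).
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  stopifnot(length(variances) == m, m >= 1)
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- if (m > 1) stats::var(estimates) else 0
  total <- w + (1 + 1 / m) * b
  se <- sqrt(total)
  df <- if (b > 0) (m - 1) * (1 + w / ((1 + 1 / m) * b))^2 else Inf
  tcrit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  tibble::tibble(estimate = qbar, within_var = w, between_var = b,
                 total_var = total, se = se, df = df,
                 ci_low = qbar - tcrit * se, ci_high = qbar + tcrit * se)
}

#' GEE fit with chained-equation covariate imputation and Rubin pooling
#'
#' Imputes missing covariates with [impute_covariates()], fits the Poisson
#' GEE on each completed dataset, and pools the log risk ratio of `term`
#' across imputations by Rubin's rules. With no missing data the pooled
#' result equals the complete-data fit exactly.
#'
#' @param data Analysis rows (missingness confined to covariates).
#' @param formula GEE model formula.
#' @param term Coefficient to pool (log2 exposure).
#' @param id Cluster column.
#' @param m,iterations,seed Imputation settings.
#' @return A tibble: pooled `rr`, `ci_low`, `ci_high`, `se`, plus the Rubin
#'   variance decomposition.
#' @export
mice_pool <- function(data, formula, term = "log2_value", id = "subject_id",
                      m = 5, iterations = 20, seed = 1L) {
  model_vars <- all.vars(formula)
  imp <- impute_covariates(data[, union(model_vars, id), drop = FALSE],
                           m = m, iterations = iterations, seed = seed,
                           exclude = id)
  ests <- imp |>
    dplyr::group_by(.data$.imp) |>
    dplyr::group_map(function(d, key) {
      fit <- fit_gee(d, formula, id = id)
      c(fit$coefficients[[term]], fit$vcov[term, term])
    })
  pooled <- pool_rubin(purrr::map_dbl(ests, 1), purrr::map_dbl(ests, 2))
  dplyr::mutate(pooled, rr = exp(.data$estimate),
                ci_low = exp(.data$ci_low), ci_high = exp(.data$ci_high),
                term = term, m = m)
}

#' Restrict DEHP aggregation to a metabolite subset
#'
#' Drops the excluded DEHP metabolites from a sample table so that
#' [derive_exposures()] recomputes the DEHP molar sum on the metabolites
#' measured in all cohorts (e.g. excluding MEHP, or MEHP and MECPP
#' postnatally).
#'
#' @param samples Urine-sample tibble with an `analyte` column.
#' @param exclude DEHP metabolite codes to drop.
#' @param registry Constants table.
#' @return The filtered tibble.
#' @export
restrict_dehp_metabolites <- function(samples, exclude = "MEHP",
                                      registry = analyte_registry()) {
  dehp_mets <- registry$metabolite_code[registry$parent_code == "DEHP"]
  stopifnot(all(exclude %in% dehp_mets))
  remaining <- setdiff(intersect(dehp_mets, unique(samples$analyte)), exclude)
  if (length(remaining) == 0) {
    stop("restriction removes every measured DEHP metabolite")
  }
  tibble::as_tibble(samples[!(samples$analyte %in% exclude), , drop = FALSE])
}

#' Compare full versus restricted DEHP metabolite sets
#'
#' Re-derives DEHP exposures with and without the excluded metabolites,
#' refits the GEE on each, and reports both risk ratios side by side.
#'
#' @param samples Standardized urine samples (with `weight` column).
#' @param outcomes,covariates Analysis inputs.
#' @param outcome Outcome name.
#' @param formula GEE formula.
#' @param exclude Metabolites to drop in the restricted set.
#' @param period Exposure period.
#' @param registry Constants table.
#' @return A two-row tibble (`set` = "full"/"restricted") of effect
#'   estimates.
#' @export
compare_dehp_restriction <- function(samples, outcomes, covariates, outcome,
                                     formula, exclude = "MEHP",
                                     period = "prenatal",
                                     registry = analyte_registry()) {
  run <- function(smp, label) {
    expo <- derive_exposures(smp, period = period, registry = registry)
    expo <- period_average(expo[expo$parent_code == "DEHP", ])
    rows <- build_prenatal_table(expo, outcomes, covariates, "DEHP", outcome)
    fit <- fit_gee(rows, formula)
    dplyr::mutate(effect_estimate(fit), set = label, .before = 1)
  }
  dplyr::bind_rows(
    run(samples, "full"),
    run(restrict_dehp_metabolites(samples, exclude, registry), "restricted"))
}
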