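#' Quantize exposure columns to integer scores
#'
#' Replaces each exposure column by its empirical-quantile score 0..q-1,
#' computed from average ranks as `floor(rank * q / (n + 1))`. Bins hold
#' approximately n/q observations up to ties; tied values always land in
#' the same bin; scores are invariant to strictly monotone transforms of a
#' compound. Rows with any missing exposure must be dropped beforehand
#' (subjects without all exposures measured are excluded from mixture
#' analyses).
#'
#' @param data Analysis rows.
#' @param compounds Character vector of exposure column names.
#' @param q Number of quantiles (>= 2).
#' @return `data` with the exposure columns replaced by integer scores and
#'   attribute `"q"`.
#' @export
quantize_exposures <- function(data, compounds, q = 4) {
  stopifnot(q >= 2)
  if (anyNA(data[, compounds])) {
    stop("missing exposure values; drop incomplete rows before quantizing")
  }
  for (cp in compounds) {
    x <- data[[cp]]
    if (length(unique(x)) < q) {
      stop("compound '", cp, "' has fewer than q = ", q, " distinct values")
    }
    sc <- floor(rank(x, ties.method = "average") * q / (length(x) + 1))
    data[[cp]] <- pmin(as.integer(sc), q - 1L)
  }
  attr(data, "q") <- q
  data
}

# Underlying log-link risk model for quantized scores: returns the fitted
# glm-style pieces needed for psi and for fast bootstrap refits.
qgc_design <- function(data, compounds, covariate_formula, outcome) {
  rhs <- paste(c(compounds, attr(stats::terms(covariate_formula), "term.labels")),
               collapse = " + ")
  if (rhs == "") rhs <- "1"
  f <- stats::as.formula(paste(outcome, "~", rhs))
  mf <- stats::model.frame(f, data = data, na.action = stats::na.omit)
  list(X = stats::model.matrix(f, mf),
       y = as.numeric(stats::model.response(mf)),
       formula = f,
       na_action = attr(mf, "na.action"))
}

fit_poisson_mat <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  if (!fit$converged || any(!is.finite(fit$coefficients))) return(NULL)
  fit
}

#' Quantile g-computation for a chemical mixture
#'
#' Fits the marginal structural model of quantile g-computation: every
#' exposure is quantized to scores 0..q-1, a log-link Poisson risk model
#' with all quantized compounds plus covariates is fitted, and the mixture
#' effect psi is the sum of the per-compound coefficients - the log risk
#' ratio for increasing all exposures by one quantile simultaneously.
#' Per-compound weights are the coefficients normalized within their sign
#' partition (absolute weights sum to 1 in each partition). Repeated
#' measures are handled by subject-clustered resampling: the confidence
#' interval is a percentile interval over `n_boot` bootstrap replicates
#' that resample subjects with replacement.
#'
#' @param data Analysis rows with one column per compound exposure
#'   (log2 or raw scale; quantization is monotone-invariant).
#' @param compounds Exposure column names.
#' @param covariate_formula One-sided formula of adjustment covariates,
#'   e.g. `~ sex + maternal_age`.
#' @param outcome Name of the binary outcome column.
#' @param id Subject (cluster) column.
#' @param q Number of quantiles (default 4: quartiles).
#' @param n_boot Bootstrap replicates for the CI.
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return An object of class `qgcomp_fit`: `psi` (log scale), `psi_rr`,
#'   `ci_low`, `ci_high`, `weights` tibble, `q`, `n_boot`,
#'   `boot_psi`, counts of dropped replicates.
#' @export
fit_qgcomp <- function(data, compounds, covariate_formula = ~ 1,
                       outcome = "status", id = "subject_id",
                       q = 4, n_boot = 1000, seed = 1L, conf_level = 0.95) {
  data <- data[stats::complete.cases(data[, compounds, drop = FALSE]), ]
  qd <- quantize_exposures(data, compounds, q = q)
  des <- qgc_design(qd, compounds, covariate_formula, outcome)
  if (!is.null(des$na_action)) qd <- qd[-des$na_action, , drop = FALSE]
  fit <- fit_poisson_mat(des$X, des$y)
  if (is.null(fit)) stop("underlying mixture model did not converge")
  betas <- fit$coefficients[compounds]
  psi <- sum(betas)
  pos <- betas[betas > 0]
  neg <- betas[betas < 0]
  weights <- tibble::tibble(
    compound = names(betas), beta = unname(betas),
    direction = ifelse(betas > 0, "positive", ifelse(betas < 0, "negative", "zero")),
    weight = dplyr::case_when(
      betas > 0 ~ betas / sum(pos),
      betas < 0 ~ betas / sum(neg),
      TRUE ~ 0))
  ids <- as.character(qd[[id]])
  subjects <- unique(ids)
  rows_by_subject <- split(seq_along(ids), ids)
  set.seed(seed)
  boot_psi <- rep(NA_real_, n_boot)
  for (bidx in seq_len(n_boot)) {
    take <- sample(subjects, length(subjects), replace = TRUE)
    idx <- unlist(rows_by_subject[take], use.names = FALSE)
    bf <- fit_poisson_mat(des$X[idx, , drop = FALSE], des$y[idx])
    if (!is.null(bf)) boot_psi[bidx] <- sum(bf$coefficients[compounds])
  }
  dropped <- sum(is.na(boot_psi))
  if (dropped > 0.1 * n_boot) {
    stop("more than 10% of bootstrap replicates failed to converge (",
         dropped, "/", n_boot, ")")
  }
  alpha2 <- (1 - conf_level) / 2
  ci <- stats::quantile(boot_psi, c(alpha2, 1 - alpha2), na.rm = TRUE, names = FALSE)
  structure(
    list(psi = psi, psi_rr = exp(psi), ci_low = exp(ci[1]), ci_high = exp(ci[2]),
         weights = weights, q = q, n_boot = n_boot, boot_psi = boot_psi,
         n_dropped = dropped, n_subjects = length(subjects), n_rows = nrow(qd),
         glm_fit = fit, compounds = compounds, conf_level = conf_level),
    class = "qgcomp_fit")
}

#' @export
print.qgcomp_fit <- function(x, ...) {
  cat("Quantile g-computation (q =", x$q, ",", x$n_boot, "bootstrap replicates)\n")
  cat(sprintf("  psi RR per one-quantile increase: %.3f (%.3f-%.3f)\n",
              x$psi_rr, x$ci_low, x$ci_high))
  cat("  subjects:", x$n_subjects, " rows:", x$n_rows, "\n")
  print(x$weights, n = Inf)
  invisible(x)
}

# Basis expansion of quantized scores for the non-linear candidates.
qgc_expand <- function(scores, spec, knots = NULL) {
  switch(spec,
    linear = matrix(scores, ncol = 1, dimnames = list(NULL, "s1")),
    quadratic = cbind(s1 = scores, s2 = scores^2),
    cubic = cbind(s1 = scores, s2 = scores^2, s3 = scores^3),
    rcs = {
      B <- rcs_basis(scores, knots)
      colnames(B) <- paste0("s", seq_len(ncol(B)))
      B
    },
    stop("unknown spec ", spec))
}

#' Non-linear mixture dose-response by quantile g-computation
#'
#' Refits the underlying quantized risk model at a finer quantization
#' (default q = 20) under several functional forms of the scores - linear,
#' quadratic, cubic polynomials and a restricted cubic spline - selects the
#' form with the best (smallest) AIC, and returns the g-computation curve:
#' the model-predicted relative risk, averaged over the observed covariate
#' distribution, of setting every exposure to joint quantile s versus
#' quantile 0.
#'
#' @inheritParams fit_qgcomp
#' @param specs Candidate functional forms.
#' @return An object of class `qgcomp_curve`: `curve` tibble
#'   (`quantile`, `rr`), `aic_table`, `selected`, and the selected fit.
#' @export
fit_qgcomp_curve <- function(data, compounds, covariate_formula = ~ 1,
                             outcome = "status", id = "subject_id", q = 20,
                             specs = c("linear", "quadratic", "cubic", "rcs")) {
  data <- data[stats::complete.cases(data[, compounds, drop = FALSE]), ]
  qd <- quantize_exposures(data, compounds, q = q)
  knots <- stats::quantile(0:(q - 1), c(0.1, 0.5, 0.9), names = FALSE)
  cov_terms <- attr(stats::terms(covariate_formula), "term.labels")
  fits <- list()
  aics <- rep(NA_real_, length(specs))
  names(aics) <- specs
  for (sp in specs) {
    aug <- qd
    cols <- character(0)
    ok <- TRUE
    for (cp in compounds) {
      B <- try(qgc_expand(qd[[cp]], sp, knots), silent = TRUE)
      if (inherits(B, "try-error")) { ok <- FALSE; break }
      nm <- paste0(".q_", cp, "_", colnames(B))
      for (j in seq_along(nm)) aug[[nm[j]]] <- B[, j]
      cols <- c(cols, nm)
    }
    if (!ok) { message("spec '", sp, "' infeasible; skipped"); next }
    rhs <- paste(c(cols, cov_terms), collapse = " + ")
    f <- stats::as.formula(paste(outcome, "~", rhs))
    g <- try(stats::glm(f, data = aug, family = stats::poisson()), silent = TRUE)
    if (inherits(g, "try-error") || !g$converged) {
      message("spec '", sp, "' did not converge; skipped")
      next
    }
    fits[[sp]] <- list(glm = g, cols = cols, spec = sp)
    aics[sp] <- stats::AIC(g)
  }
  if (all(is.na(aics))) stop("no candidate specification could be fitted")
  selected <- names(which.min(aics))
  best <- fits[[selected]]
  curve <- purrr::map_dfr(0:(q - 1), function(s) {
    nd <- qd
    for (cp in compounds) {
      B <- qgc_expand(rep(s, nrow(qd)), best$spec, knots)
      nm <- paste0(".q_", cp, "_", colnames(B))
      for (j in seq_along(nm)) nd[[nm[j]]] <- B[, j]
    }
    tibble::tibble(quantile = s,
                   mean_risk = mean(stats::predict(best$glm, newdata = nd,
                                                   type = "response")))
  })
  curve$rr <- curve$mean_risk / curve$mean_risk[curve$quantile == 0]
  structure(
    list(curve = curve[, c("quantile", "rr", "mean_risk")],
         aic_table = tibble::tibble(spec = names(aics), aic = unname(aics),
                                    selected = names(aics) == selected),
         selected = selected, q = q, fit = best$glm),
    class = "qgcomp_curve")
}

#' @export
print.qgcomp_curve <- function(x, ...) {
  cat("Mixture dose-response (quantile g-computation, q =", x$q, ")\n")
  cat("  selected specification:", x$selected, "\n")
  print(x$aic_table)
  invisible(x)
}

#' Sex effect-measure modification of the mixture effect
#'
#' Interacts every quantized compound with sex in the underlying model and
#' reports per-sex mixture effects psi (sums of the sex-specific compound
#' coefficients) with subject-clustered bootstrap percentile intervals; the
#' interaction p-value is the bootstrap two-sided p for the psi difference.
#'
#' @inheritParams fit_qgcomp
#' @param sex_var Name of the two-level sex column.
#' @return A list with `estimates` (per-sex psi RRs and CIs),
#'   `p_interaction`, and bootstrap draws.
#' @export
fit_qgcomp_emm <- function(data, compounds, covariate_formula = ~ 1,
                           outcome = "status", id = "subject_id",
                           sex_var = "sex", q = 4, n_boot = 500, seed = 1L) {
  sx <- as.factor(data[[sex_var]])
  if (nlevels(droplevels(sx)) < 2) stop("both sexes must be present")
  data <- data[stats::complete.cases(data[, compounds, drop = FALSE]), ]
  qd <- quantize_exposures(data, compounds, q = q)
  lv <- levels(droplevels(as.factor(qd[[sex_var]])))
  ind2 <- as.integer(qd[[sex_var]] == lv[2])
  cov_terms <- attr(stats::terms(covariate_formula), "term.labels")
  int_cols <- paste0(".i_", compounds)
  for (j in seq_along(compounds)) qd[[int_cols[j]]] <- qd[[compounds[j]]] * ind2
  rhs <- paste(c(compounds, int_cols, sex_var, cov_terms), collapse = " + ")
  f <- stats::as.formula(paste(outcome, "~", rhs))
  mf <- stats::model.frame(f, data = qd, na.action = stats::na.omit)
  X <- stats::model.matrix(f, mf)
  y <- as.numeric(stats::model.response(mf))
  keep <- seq_len(nrow(qd))
  if (!is.null(attr(mf, "na.action"))) keep <- keep[-attr(mf, "na.action")]
  qd <- qd[keep, , drop = FALSE]
  psi_pair <- function(cf) {
    p1 <- sum(cf[compounds])
    p2 <- p1 + sum(cf[int_cols])
    c(p1, p2)
  }
  fit <- fit_poisson_mat(X, y)
  if (is.null(fit)) stop("underlying interaction model did not converge")
  psis <- psi_pair(fit$coefficients)
  ids <- as.character(qd[[id]])
  subjects <- unique(ids)
  rows_by_subject <- split(seq_along(ids), ids)
  set.seed(seed)
  bp <- matrix(NA_real_, n_boot, 2)
  for (bidx in seq_len(n_boot)) {
    take <- sample(subjects, length(subjects), replace = TRUE)
    idx <- unlist(rows_by_subject[take], use.names = FALSE)
    bf <- fit_poisson_mat(X[idx, , drop = FALSE], y[idx])
    if (!is.null(bf)) bp[bidx, ] <- psi_pair(bf$coefficients)
  }
  ok <- stats::complete.cases(bp)
  dd <- bp[ok, 2] - bp[ok, 1]
  p_int <- 2 * min(mean(dd <= 0), mean(dd >= 0))
  p_int <- min(1, max(p_int, 2 / (sum(ok) + 1)))
  est <- tibble::tibble(
    sex = lv, psi = psis, psi_rr = exp(psis),
    ci_low = exp(apply(bp[ok, , drop = FALSE], 2, stats::quantile, 0.025)),
    ci_high = exp(apply(bp[ok, , drop = FALSE], 2, stats::quantile, 0.975)))
  list(estimates = est, p_interaction = p_int, boot_psi = bp)
}
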