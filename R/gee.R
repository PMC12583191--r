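#' Poisson GEE with exchangeable working correlation
#'
#' Fits a log-link Poisson marginal model to clustered (repeated-measures)
#' binary or count outcomes by generalized estimating equations with an
#' exchangeable working correlation, and reports robust (sandwich) standard
#' errors. With a log2-transformed exposure in the linear predictor, the
#' exponentiated coefficient is the risk ratio per doubling of exposure.
#'
#' The exchangeable correlation alpha and the dispersion are re-estimated by
#' moment updates at each Fisher-scoring step; iteration stops when the
#' relative change in coefficients falls below `tol`. Clusters of size one
#' make the working correlation vacuous, in which case the fit coincides
#' with an independence Poisson GLM with heteroskedasticity-robust standard
#' errors.
#'
#' @param data A data frame (one row per observation).
#' @param formula Model formula, e.g. `status ~ log2_value + sex + cohort_id`.
#' @param id Name of the cluster (subject) column.
#' @param weights Optional name of a per-observation weight column
#'   (constant within cluster), e.g. stabilized selection weights.
#' @param tol Convergence tolerance on the relative coefficient change.
#' @param maxit Maximum Fisher-scoring iterations.
#' @return An object of class `gee_fit` with components `coefficients`,
#'   `vcov` (robust), `alpha`, `dispersion`, `n_obs`, `n_clusters`,
#'   `converged`.
#' @export
fit_gee <- function(data, formula, id = "subject_id", weights = NULL,
                    tol = 1e-8, maxit = 200) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  X <- stats::model.matrix(formula, mf)
  y <- as.numeric(stats::model.response(mf))
  used <- seq_len(nrow(data))
  omit <- attr(mf, "na.action")
  if (!is.null(omit)) used <- used[-omit]
  cl <- as.factor(data[[id]][used])
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(data[[weights]][used])
  if (nlevels(droplevels(cl)) < 2) stop("need at least 2 clusters")
  eng <- gee_engine(X, y, droplevels(cl), w, tol = tol, maxit = maxit)
  structure(
    c(eng, list(formula = formula, terms = stats::terms(mf),
                xlevels = stats::.getXlevels(stats::terms(mf), mf),
                id = id, call = match.call())),
    class = "gee_fit")
}

# Vectorized estimating-equation engine. The exchangeable inverse
# R^-1 = c1 I + c2 J is exploited in closed form, so all cluster sums reduce
# to rowsum() calls and the fit scales linearly in the number of rows.
gee_engine <- function(X, y, cl, w, tol = 1e-8, maxit = 200) {
  p <- ncol(X)
  n <- length(y)
  ni <- as.vector(table(cl))
  start <- suppressWarnings(
    stats::glm.fit(X, y, weights = w, family = stats::poisson())$coefficients)
  beta <- ifelse(is.na(start), 0, start)
  alpha <- 0
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    if (max(abs(beta)) > 50 || max(eta) > 30) {
      stop("GEE coefficients diverging; data may be completely separated")
    }
    mu <- exp(eta)
    s <- sqrt(mu)
    e <- y - mu
    r <- e / s
    phi <- sum(w * r^2) / (n - p)
    sum_r <- rowsum(r * w, cl)
    sum_r2 <- rowsum(r^2 * w, cl)
    pairs <- sum(ni * (ni - 1))
    alpha <- if (pairs > p) {
      max(0, min(0.95, sum(sum_r^2 / rowsum(w, cl) * ni - sum_r2) /
                   (phi * (pairs - p))))
    } else 0
    c1 <- 1 / (1 - alpha)
    c2 <- -alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
    A <- rowsum(w * s * X, cl)
    b <- drop(rowsum(w * e / s, cl))
    H <- c1 * crossprod(X, w * mu * X) + crossprod(A, c2 * A)
    U <- c1 * crossprod(X, w * e) + crossprod(A, c2 * b)
    step <- solve(H, U)
    beta_new <- beta + drop(step)
    delta <- max(abs(beta_new - beta)) / max(1, max(abs(beta)))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  s <- sqrt(mu)
  e <- y - mu
  c1 <- 1 / (1 - alpha)
  c2 <- -alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
  A <- rowsum(w * s * X, cl)
  b <- drop(rowsum(w * e / s, cl))
  H <- c1 * crossprod(X, w * mu * X) + crossprod(A, c2 * A)
  G <- c1 * rowsum(w * e * X, cl) + (c2 * b) * A
  Hinv <- solve(H)
  V <- Hinv %*% crossprod(G) %*% Hinv
  dimnames(V) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  list(coefficients = beta, vcov = V, alpha = alpha,
       dispersion = sum(w * (e / s)^2) / (n - p),
       n_obs = n, n_clusters = length(ni), converged = converged,
       fitted = mu, model_matrix_names = colnames(X))
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("Poisson GEE (exchangeable), robust SEs\n")
  cat("  clusters:", x$n_clusters, " observations:", x$n_obs,
      " alpha:", signif(x$alpha, 3),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  print(tidy.gee_fit(x), n = Inf)
  invisible(x)
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$vcov

#' Risk ratio per exposure doubling
#'
#' Inverse of the log-link coefficient map when the exposure regressor is
#' log2-transformed: `RR = exp(beta)`.
#'
#' @param beta_log2 Coefficient(s) on a log2-scale exposure.
#' @return Risk ratio(s) per doubling.
#' @export
rr_per_doubling <- function(beta_log2) {
  stopifnot(all(is.finite(beta_log2)))
  exp(beta_log2)
}

#' Extract a risk-ratio effect estimate from a GEE fit
#'
#' @param fit A `gee_fit`.
#' @param term Coefficient name (default the log2 exposure).
#' @param conf_level Confidence level for the Wald interval on the log
#'   scale.
#' @return A one-row tibble: `term`, `rr`, `ci_low`, `ci_high`,
#'   `robust_se`, `n_subjects`, `n_rows`.
#' @export
effect_estimate <- function(fit, term = "log2_value", conf_level = 0.95) {
  if (!term %in% names(fit$coefficients)) {
    stop("term '", term, "' not in the model")
  }
  b <- fit$coefficients[[term]]
  se <- sqrt(fit$vcov[term, term])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(term = term, rr = exp(b), ci_low = exp(b - z * se),
                 ci_high = exp(b + z * se), robust_se = se,
                 n_subjects = fit$n_clusters, n_rows = fit$n_obs)
}

#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline (linear beyond the boundary
#' knots). With k knots the basis has k - 1 columns: the identity plus
#' k - 2 non-linear terms.
#'
#' @param x Numeric vector.
#' @param knots Knot locations (default: 10th, 50th, 90th percentiles of
#'   `x`).
#' @return A matrix with attribute `"knots"`.
#' @export
rcs_basis <- function(x, knots = stats::quantile(x, c(0.1, 0.5, 0.9))) {
  knots <- sort(unname(knots))
  if (anyDuplicated(knots)) {
    stop("coincident spline knots; use fewer knots or more distinct exposure values")
  }
  k <- length(knots)
  tk <- knots[k]
  tk1 <- knots[k - 1]
  pp <- function(u) pmax(u, 0)^3
  B <- matrix(x, ncol = 1)
  for (j in seq_len(k - 2)) {
    B <- cbind(B, (pp(x - knots[j]) -
                     pp(x - tk1) * (tk - knots[j]) / (tk - tk1) +
                     pp(x - tk) * (tk1 - knots[j]) / (tk - tk1)) /
                 (tk - knots[1])^2)
  }
  colnames(B) <- c("lin", paste0("nl", seq_len(k - 2)))
  attr(B, "knots") <- knots
  B
}

#' Spline dose-response curve with a non-linearity test
#'
#' Replaces the linear exposure term by a restricted cubic spline (3 knots
#' at the exposure's 10th, 50th and 90th percentiles by default) inside the
#' Poisson GEE, tests the non-linear spline coefficients with a robust Wald
#' test, and returns the predicted relative risk across the exposure range
#' with covariates held fixed (continuous covariates at their means,
#' categoricals at their reference level; these cancel in the ratio, which
#' is normalized to 1 at the reference exposure).
#'
#' @param data Analysis rows.
#' @param formula Covariate-only right-hand side with the outcome on the
#'   left, e.g. `status ~ sex + maternal_age`; the exposure enters via
#'   `exposure`.
#' @param exposure Name of the (log2-scale) exposure column.
#' @param id Cluster column.
#' @param knot_quantiles Quantiles at which to place the three knots.
#' @param ref_quantile Exposure quantile used as the curve's reference
#'   (relative risk 1).
#' @param grid_length Number of grid points.
#' @return An object of class `dose_response`: list with `curve` (tibble
#'   `exposure`, `rr`, `ci_low`, `ci_high`), `p_nonlinearity`, and the
#'   underlying `fit`.
#' @export
fit_dose_response <- function(data, formula, exposure = "log2_value",
                              id = "subject_id",
                              knot_quantiles = c(0.1, 0.5, 0.9),
                              ref_quantile = 0.5, grid_length = 50) {
  x <- data[[exposure]]
  knots <- stats::quantile(x, knot_quantiles, names = FALSE)
  B <- rcs_basis(x, knots)
  bn <- paste0(".rcs_", colnames(B))
  aug <- data
  for (j in seq_along(bn)) aug[[bn[j]]] <- B[, j]
  f2 <- stats::update(formula, paste("~ . +", paste(bn, collapse = " + ")))
  fit <- fit_gee(aug, f2, id = id)
  nl <- bn[-1]
  bvec <- fit$coefficients[nl]
  Vnl <- fit$vcov[nl, nl, drop = FALSE]
  stat <- drop(t(bvec) %*% solve(Vnl, bvec))
  p_nl <- stats::pchisq(stat, df = length(nl), lower.tail = FALSE)
  ref <- stats::quantile(x, ref_quantile, names = FALSE)
  grid <- seq(min(x), max(x), length.out = grid_length)
  Bg <- rcs_basis(grid, knots)
  Br <- rcs_basis(ref, knots)
  Cmat <- sweep(Bg, 2, drop(Br), `-`)
  est <- drop(Cmat %*% fit$coefficients[bn])
  se <- sqrt(rowSums((Cmat %*% fit$vcov[bn, bn]) * Cmat))
  structure(
    list(curve = tibble::tibble(exposure = grid, rr = exp(est),
                                ci_low = exp(est - 1.96 * se),
                                ci_high = exp(est + 1.96 * se)),
         p_nonlinearity = p_nl, reference = ref, knots = knots,
         exposure = exposure, fit = fit),
    class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("Dose-response curve (restricted cubic spline, GEE)\n")
  cat("  knots:", paste(signif(x$knots, 3), collapse = ", "),
      "| reference:", signif(x$reference, 3), "\n")
  cat("  p (non-linearity, robust Wald):", format.pval(x$p_nonlinearity), "\n")
  invisible(x)
}

#' Effect-measure modification by sex
#'
#' Adds an exposure-by-sex interaction to the GEE model and reports
#' stratum-specific risk ratios per doubling as contrasts of the
#' interaction model, with the interaction p-value from the robust Wald
#' test.
#'
#' @param data Analysis rows with a two-level `sex` column.
#' @param formula Model with the exposure term, e.g.
#'   `status ~ log2_value + sex + maternal_age`.
#' @param exposure Exposure column name.
#' @param sex_var Name of the sex column.
#' @param id Cluster column.
#' @return A list with `estimates` (tibble of per-sex risk ratios) and
#'   `p_interaction`.
#' @export
fit_sex_emm <- function(data, formula, exposure = "log2_value",
                        sex_var = "sex", id = "subject_id") {
  sx <- data[[sex_var]]
  if (length(unique(stats::na.omit(sx))) < 2) {
    stop("both sexes must be present for effect-measure modification")
  }
  f2 <- stats::update(formula,
                      paste("~ . +", exposure, ":", sex_var))
  fit <- fit_gee(data, f2, id = id)
  lv <- levels(as.factor(sx))
  int_term <- grep(paste0("^", exposure, ":", sex_var), names(fit$coefficients),
                   value = TRUE)
  if (length(int_term) != 1) {
    int_term <- grep(paste0("^", sex_var, ".*:", exposure, "$"),
                     names(fit$coefficients), value = TRUE)
  }
  b_main <- fit$coefficients[[exposure]]
  b_int <- fit$coefficients[[int_term]]
  se_main <- sqrt(fit$vcov[exposure, exposure])
  v_sum <- fit$vcov[exposure, exposure] + fit$vcov[int_term, int_term] +
    2 * fit$vcov[exposure, int_term]
  est <- tibble::tibble(
    sex = lv,
    rr = c(exp(b_main), exp(b_main + b_int)),
    ci_low = c(exp(b_main - 1.96 * se_main),
               exp(b_main + b_int - 1.96 * sqrt(v_sum))),
    ci_high = c(exp(b_main + 1.96 * se_main),
                exp(b_main + b_int + 1.96 * sqrt(v_sum))))
  z <- b_int / sqrt(fit$vcov[int_term, int_term])
  list(estimates = est, p_interaction = 2 * stats::pnorm(-abs(z)), fit = fit)
}

#' Trimester-stratified GEE fits
#'
#' Fits one Poisson GEE per trimester on the subjects with exposure in that
#' trimester. Empty trimesters are skipped with a message.
#'
#' @param trimester_exposures Output of [trimester_average()].
#' @param outcomes Harmonized outcome records.
#' @param covariates Per-subject covariates.
#' @param compound,outcome Selection.
#' @param formula Model formula for the analysis rows.
#' @param covariate_names Covariates required complete.
#' @param id Cluster column.
#' @return A tibble of per-trimester effect estimates.
#' @export
fit_by_trimester <- function(trimester_exposures, outcomes, covariates,
                             compound, outcome, formula,
                             covariate_names = setdiff(names(covariates), "subject_id"),
                             id = "subject_id") {
  out <- purrr::map(sort(unique(trimester_exposures$trimester)), function(tr) {
    expt <- trimester_exposures[trimester_exposures$trimester == tr, ]
    expt$timing <- tr
    rows <- build_prenatal_table(expt, outcomes, covariates, compound, outcome,
                                 covariate_names = covariate_names)
    if (nrow(rows) == 0) {
      message("trimester ", tr, ": no analysable rows; skipped")
      return(NULL)
    }
    fit <- fit_gee(rows, formula, id = id)
    dplyr::mutate(effect_estimate(fit), trimester = tr, .before = 1)
  })
  dplyr::bind_rows(out)
}
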