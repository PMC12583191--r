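#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Poisson GEE fit
#'
#' @param x A `gee_fit`.
#' @param exponentiate Report risk ratios instead of log coefficients.
#' @param conf_level Confidence level for Wald intervals on the log scale.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `robust_se`, `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.gee_fit <- function(x, exponentiate = FALSE, conf_level = 0.95, ...) {
  b <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- b / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- b - q * se
  hi <- b + q * se
  if (exponentiate) { b <- exp(b); lo <- exp(lo); hi <- exp(hi) }
  tibble::tibble(term = names(x$coefficients), estimate = unname(b),
                 robust_se = unname(se), statistic = unname(z),
                 p.value = 2 * stats::pnorm(-abs(unname(z))),
                 conf.low = unname(lo), conf.high = unname(hi))
}

#' @rdname tidy.gee_fit
#' @export
glance.gee_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_clusters = x$n_clusters,
                 alpha = x$alpha, dispersion = x$dispersion,
                 converged = x$converged)
}

#' Tidy a quantile g-computation fit
#'
#' @param x A `qgcomp_fit`.
#' @param ... Unused.
#' @return Per-compound weights (`compound`, `beta`, `direction`,
#'   `weight`).
#' @export
tidy.qgcomp_fit <- function(x, ...) x$weights

#' @rdname tidy.qgcomp_fit
#' @export
glance.qgcomp_fit <- function(x, ...) {
  tibble::tibble(psi = x$psi, psi_rr = x$psi_rr, ci_low = x$ci_low,
                 ci_high = x$ci_high, q = x$q, n_boot = x$n_boot,
                 n_dropped = x$n_dropped, n_subjects = x$n_subjects,
                 n_rows = x$n_rows)
}

#' Tidy a random-effects meta-analysis
#'
#' @param x A `meta_fit`.
#' @param ... Unused.
#' @return The per-cohort estimates.
#' @export
tidy.meta_fit <- function(x, ...) x$per_cohort

#' @rdname tidy.meta_fit
#' @export
glance.meta_fit <- function(x, ...) {
  tibble::tibble(pooled_rr = x$pooled_rr, ci_low = x$ci_low,
                 ci_high = x$ci_high, tau2 = x$tau2, i2 = x$i2,
                 q_stat = x$q, k = x$k)
}

#' Plot a spline dose-response curve
#'
#' @param object A `dose_response` from [fit_dose_response()].
#' @param ... Unused.
#' @return A ggplot: relative risk (log scale) against exposure, with the
#'   pointwise confidence band and the non-linearity p-value in the
#'   subtitle.
#' @export
autoplot.dose_response <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$exposure, y = .data$rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "log2 exposure", y = "Relative risk",
                  subtitle = sprintf("p (non-linearity) = %s",
                                     format.pval(object$p_nonlinearity, digits = 2))) +
    ggplot2::theme_minimal()
}

#' Plot a mixture dose-response curve
#'
#' @param object A `qgcomp_curve` from [fit_qgcomp_curve()].
#' @param ... Unused.
#' @return A ggplot of relative risk against joint exposure quantile.
#' @export
autoplot.qgcomp_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$quantile, y = .data$rr)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Joint exposure quantile", y = "Relative risk",
                  subtitle = paste("selected specification:", object$selected)) +
    ggplot2::theme_minimal()
}

#' Forest plot of cohort-stratified estimates
#'
#' @param object A `meta_fit` from [random_effects_meta()].
#' @param ... Unused.
#' @return A ggplot forest plot with the pooled estimate as a dashed line.
#' @export
autoplot.meta_fit <- function(object, ...) {
  d <- dplyr::mutate(object$per_cohort, rr = exp(.data$log_rr),
                     lo = exp(.data$log_rr - 1.96 * .data$se),
                     hi = exp(.data$log_rr + 1.96 * .data$se))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rr, y = .data$cohort_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = object$pooled_rr, linetype = 2) +
    ggplot2::geom_vline(xintercept = 1, colour = "grey60") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Risk ratio", y = NULL,
                  subtitle = sprintf("pooled RR %.2f; I2 = %.0f%%",
                                     object$pooled_rr, object$i2)) +
    ggplot2::theme_minimal()
}

#' Bar plot of mixture weights
#'
#' @param x A `qgcomp_fit`.
#' @return A ggplot of signed per-compound weights.
#' @export
plot_mixture_weights <- function(x) {
  ggplot2::ggplot(x$weights,
                  ggplot2::aes(x = stats::reorder(.data$compound, .data$beta),
                               y = .data$beta, fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Coefficient (log RR per quantile)") +
    ggplot2::theme_minimal()
}
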