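#' Harmonize cohort outcome codings to binary status
#'
#' Maps cohort-specific outcome codings (questionnaire responses or
#' clinician classifications, e.g. "definite"/"possible"/"no") to the four
#' binary outcomes analysed across cohorts. Codes absent from the mapping
#' raise an error listing them; records with a missing assessment should be
#' absent rows, not mapped.
#'
#' @param outcome_table Tibble with `subject_id`, `outcome`,
#'   `age_at_assessment` and a raw `code` column.
#' @param mapping Named list (or named logical vector) from code to case
#'   status, e.g. `list(definite = TRUE, possible = FALSE, no = FALSE)`.
#' @return A tibble of harmonized records with a logical `status` column.
#' @export
harmonize_outcomes <- function(outcome_table, mapping) {
  mapping <- unlist(mapping)
  unknown <- setdiff(unique(outcome_table$code), names(mapping))
  if (length(unknown) > 0) {
    stop("unmapped outcome code(s): ", paste(unknown, collapse = ", "))
  }
  out <- dplyr::mutate(outcome_table,
                       status = unname(mapping[.data$code]))
  out$code <- NULL
  tibble::as_tibble(out)
}

#' Build the prenatal analysis table
#'
#' One row per subject and outcome assessment: the subject's (averaged)
#' prenatal exposure is repeated across their outcome records, covariates
#' are joined, and the complete-case filter drops rows with any missing
#' model covariate. Subjects lacking the exposure or all outcome
#' assessments contribute no rows.
#'
#' @param exposures One exposure record per subject and compound (use
#'   [period_average()] first).
#' @param outcomes Harmonized outcome records.
#' @param covariates Per-subject covariate table.
#' @param compound Parent compound to select.
#' @param outcome Outcome to select.
#' @param covariate_names Covariates to require complete (default: all
#'   non-id columns of `covariates`).
#' @return An analysis tibble with `subject_id`, `log2_value`, `status`,
#'   `age_at_assessment` and the covariates.
#' @export
build_prenatal_table <- function(exposures, outcomes, covariates,
                                 compound, outcome,
                                 covariate_names = setdiff(names(covariates), "subject_id")) {
  exp1 <- exposures[exposures$parent_code == compound, ]
  if (anyDuplicated(exp1$subject_id)) {
    stop("expected one prenatal exposure per subject; run period_average() first")
  }
  oc <- outcomes[outcomes$outcome == outcome, ]
  rows <- dplyr::inner_join(
    exp1[, c("subject_id", "cohort_id", "parent_code", "log2_value", "value", "scale")],
    oc[, c("subject_id", "age_at_assessment", "status")],
    by = "subject_id")
  rows <- dplyr::left_join(rows, covariates, by = "subject_id")
  keep <- stats::complete.cases(rows[, covariate_names, drop = FALSE])
  out <- rows[keep, , drop = FALSE]
  out$outcome <- outcome
  tibble::as_tibble(dplyr::arrange(out, .data$subject_id, .data$age_at_assessment))
}

#' Build the lagged postnatal analysis table
#'
#' Pairs each repeated postnatal exposure with the outcomes that follow it:
#' for an exposure measured at time t with the next exposure at t', all
#' assessments with age in (t, t'] form t's outcome window (the last
#' exposure's window extends to age 5). A window is a case when any
#' assessment in it is positive; its `age_at_assessment` covariate is the
#' mean assessment age in the window. Windows without any assessment
#' produce no row, so every row satisfies exposure time < outcome age.
#'
#' @param exposures Postnatal exposure records (repeated per subject).
#' @param outcomes Harmonized outcome records.
#' @param covariates Per-subject covariate table.
#' @param compound,outcome Selection as in [build_prenatal_table()].
#' @param covariate_names Covariates required complete.
#' @param horizon Upper age bound for the last window (years).
#' @return An analysis tibble with one row per subject and exposure window,
#'   including `window_id` and `exposure_timing`.
#' @export
build_postnatal_table <- function(exposures, outcomes, covariates,
                                  compound, outcome,
                                  covariate_names = setdiff(names(covariates), "subject_id"),
                                  horizon = 5) {
  exp1 <- exposures[exposures$parent_code == compound, ]
  exp1 <- exp1[order(exp1$subject_id, exp1$timing), ]
  exp1 <- exp1 |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(window_id = dplyr::row_number()) |>
    dplyr::ungroup()
  oc <- outcomes[outcomes$outcome == outcome &
                   outcomes$subject_id %in% exp1$subject_id, ]
  oc <- oc[oc$age_at_assessment <= horizon, ]
  # assign each assessment to its half-open exposure window (t, t']
  times_by_subj <- split(exp1$timing, exp1$subject_id)
  oc_split <- split(seq_len(nrow(oc)), oc$subject_id)
  win <- integer(nrow(oc))
  for (sid in names(oc_split)) {
    ii <- oc_split[[sid]]
    win[ii] <- findInterval(oc$age_at_assessment[ii], times_by_subj[[sid]],
                            left.open = TRUE)
  }
  oc$window_id <- win
  oc <- oc[oc$window_id > 0, ]
  agg <- oc |>
    dplyr::group_by(.data$subject_id, .data$window_id) |>
    dplyr::summarise(status = any(.data$status),
                     age_at_assessment = mean(.data$age_at_assessment),
                     n_assessments = dplyr::n(), .groups = "drop")
  rows <- dplyr::inner_join(
    dplyr::transmute(exp1, .data$subject_id, .data$cohort_id, .data$window_id,
                     exposure_timing = .data$timing, .data$log2_value,
                     .data$value, .data$scale),
    agg, by = c("subject_id", "window_id"))
  rows <- dplyr::left_join(rows, covariates, by = "subject_id")
  keep <- stats::complete.cases(rows[, covariate_names, drop = FALSE])
  out <- rows[keep, , drop = FALSE]
  out$outcome <- outcome
  out$parent_code <- compound
  tibble::as_tibble(dplyr::arrange(out, .data$subject_id, .data$window_id))
}

#' Build a mixture analysis table
#'
#' Spreads the exposure records of the mixture compounds into one column of
#' log2 values per compound, drops subjects without all compounds measured,
#' and aligns outcomes: prenatal tables repeat the subject's (averaged)
#' exposures across assessments; postnatal tables use the lagged half-open
#' windows of [build_postnatal_table()] with all compounds sharing the
#' window's exposure time.
#'
#' @param exposures Exposure records ([period_average()]d for prenatal).
#' @param outcomes Harmonized outcome records.
#' @param covariates Per-subject covariate table.
#' @param compounds Parent compounds of the mixture.
#' @param outcome Outcome to select.
#' @param covariate_names Covariates required complete.
#' @param horizon Upper age bound for the last postnatal window.
#' @return An analysis tibble with one log2-exposure column per compound.
#' @export
build_mixture_table <- function(exposures, outcomes, covariates, compounds,
                                outcome,
                                covariate_names = setdiff(names(covariates), "subject_id"),
                                horizon = 5) {
  period <- exposures$period[1]
  wide <- exposures |>
    dplyr::filter(.data$parent_code %in% compounds) |>
    dplyr::select("subject_id", "cohort_id", "timing", "parent_code",
                  "log2_value") |>
    tidyr::pivot_wider(names_from = "parent_code", values_from = "log2_value")
  wide <- wide[stats::complete.cases(wide[, compounds, drop = FALSE]), ]
  oc <- outcomes[outcomes$outcome == outcome, ]
  if (period == "prenatal") {
    rows <- dplyr::inner_join(wide, oc[, c("subject_id", "age_at_assessment",
                                           "status")], by = "subject_id")
  } else {
    wide <- wide[order(wide$subject_id, wide$timing), ]
    wide <- wide |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::mutate(window_id = dplyr::row_number()) |>
      dplyr::ungroup()
    oc <- oc[oc$subject_id %in% wide$subject_id &
               oc$age_at_assessment <= horizon, ]
    times_by_subj <- split(wide$timing, wide$subject_id)
    oc_split <- split(seq_len(nrow(oc)), oc$subject_id)
    win <- integer(nrow(oc))
    for (sid in names(oc_split)) {
      ii <- oc_split[[sid]]
      win[ii] <- findInterval(oc$age_at_assessment[ii], times_by_subj[[sid]],
                              left.open = TRUE)
    }
    oc$window_id <- win
    oc <- oc[oc$window_id > 0, ]
    agg <- oc |>
      dplyr::group_by(.data$subject_id, .data$window_id) |>
      dplyr::summarise(status = any(.data$status),
                       age_at_assessment = mean(.data$age_at_assessment),
                       .groups = "drop")
    rows <- dplyr::inner_join(wide, agg, by = c("subject_id", "window_id"))
  }
  rows <- dplyr::left_join(rows, covariates, by = "subject_id")
  keep <- stats::complete.cases(rows[, covariate_names, drop = FALSE])
  out <- rows[keep, , drop = FALSE]
  out$outcome <- outcome
  tibble::as_tibble(out)
}
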