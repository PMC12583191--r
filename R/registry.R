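#' Analyte constants registry
#'
#' Loads the table of chemical constants used throughout the pipeline: the
#' metabolite-to-parent mapping, molecular weights of metabolite and parent
#' diester (g/mol), the molar fractional urinary excretion (FUE) of each
#' metabolite, the analyte class (phthalate or bisphenol) and whether the
#' analyte is eligible for estimated-daily-intake derivation. MCPP is a
#' non-specific metabolite of several high-molecular-weight phthalates and is
#' analysed on the urinary-concentration scale, so it is flagged
#' `is_edi_eligible = FALSE`.
#'
#' Molecular weights follow the molecular formulas; FUE defaults are the
#' values in common use in the biomonitoring literature. Both can be
#' overridden by supplying a custom table with the same columns.
#'
#' @param path Path to a TSV file with columns `metabolite_code`,
#'   `parent_code`, `mw_metabolite`, `mw_parent`, `fue`, `analyte_class`,
#'   `is_edi_eligible`. Defaults to the table shipped with the package.
#' @return A tibble with one row per metabolite, carrying an attribute
#'   `registry_version`.
#' @export
#' @examples
#' reg <- analyte_registry()
#' lookup_analyte("MnBP", reg)$parent_code
analyte_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "analyte_constants.tsv", package = "phthalmix")
  }
  reg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("metabolite_code", "parent_code", "mw_metabolite", "mw_parent",
                "fue", "analyte_class", "is_edi_eligible")
  missing_cols <- setdiff(required, names(reg))
  if (length(missing_cols) > 0) {
    stop("registry table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(reg$metabolite_code)) {
    stop("registry has duplicated metabolite codes")
  }
  stopifnot(all(reg$mw_metabolite > 0), all(reg$mw_parent > 0),
            all(reg$fue > 0 & reg$fue <= 1))
  attr(reg, "registry_version") <- "1.0"
  reg
}

#' Look up one analyte definition
#'
#' @param metabolite_code Metabolite short code, e.g. `"MnBP"`.
#' @param registry A registry tibble from [analyte_registry()].
#' @return A one-row tibble with the analyte's constants.
#' @export
lookup_analyte <- function(metabolite_code, registry = analyte_registry()) {
  stopifnot(length(metabolite_code) == 1L)
  hit <- registry[registry$metabolite_code == metabolite_code, ]
  if (nrow(hit) != 1L) {
    stop("unknown analyte code: '", metabolite_code, "'")
  }
  hit
}

#' Filter analytes by detection rate
#'
#' Applies the inclusion rule used when pooling assay panels: phthalates are
#' retained when detected in more than 50% of samples, bisphenols when
#' detected in more than 10% (both strict inequalities, reflecting the lower
#' detection rates typical of bisphenol assays).
#'
#' @param detection A data frame with columns `analyte`, `analyte_class`
#'   (`"phthalate"` or `"bisphenol"`) and `detection_rate` in \[0, 1\].
#' @param phthalate_min,bisphenol_min Strict lower bounds on the detection
#'   rate per class.
#' @return The retained rows, as a tibble.
#' @export
apply_detection_filter <- function(detection, phthalate_min = 0.5,
                                   bisphenol_min = 0.1) {
  stopifnot(all(c("analyte", "analyte_class", "detection_rate") %in% names(detection)))
  if (any(detection$detection_rate < 0 | detection$detection_rate > 1)) {
    stop("detection rates must lie in [0, 1]")
  }
  if (!all(detection$analyte_class %in% c("phthalate", "bisphenol"))) {
    stop("analyte_class must be 'phthalate' or 'bisphenol'")
  }
  keep <- ifelse(detection$analyte_class == "phthalate",
                 detection$detection_rate > phthalate_min,
                 detection$detection_rate > bisphenol_min)
  tibble::as_tibble(detection[keep, , drop = FALSE])
}

#' Filter cohorts by size and covariate completeness
#'
#' Cohorts with fewer than 30 participants, or in which more than 50% of
#' participants have missing covariate data, are excluded from pooling.
#'
#' @param cohort_summaries Data frame with columns `cohort_id`, `n` and
#'   `missing_covariate_fraction`.
#' @return The retained rows, as a tibble.
#' @export
apply_cohort_filter <- function(cohort_summaries) {
  stopifnot(all(c("cohort_id", "n", "missing_covariate_fraction") %in%
                  names(cohort_summaries)))
  stopifnot(all(cohort_summaries$n >= 0),
            all(cohort_summaries$missing_covariate_fraction >= 0),
            all(cohort_summaries$missing_covariate_fraction <= 1))
  keep <- cohort_summaries$n >= 30 &
    cohort_summaries$missing_covariate_fraction <= 0.5
  tibble::as_tibble(cohort_summaries[keep, , drop = FALSE])
}

#' Read cohort assay profiles
#'
#' Cohort profiles describe how each cohort's urine samples were assayed and
#' pre-processed: the dilution variable (specific gravity or creatinine),
#' whether concentrations are adjusted for time of day at sampling, which
#' metabolites the panel measured, and the per-analyte limit of detection.
#'
#' @param path Path to a YAML file mapping cohort ids to profiles. Defaults
#'   to the profiles shipped with the package.
#' @return A tibble with one row per cohort and list-columns
#'   `analytes_measured` and `lod_per_analyte`.
#' @export
read_cohort_profiles <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_profiles.yaml", package = "phthalmix")
  }
  raw <- yaml::read_yaml(path)
  rows <- purrr::imap(raw, function(p, id) {
    if (!p$dilution_variable %in% c("specific_gravity", "creatinine")) {
      stop("cohort '", id, "': dilution_variable must be specific_gravity or creatinine")
    }
    lods <- unlist(p$lod_per_analyte)
    if (!all(names(lods) %in% p$analytes_measured)) {
      stop("cohort '", id, "': LOD given for an analyte not in analytes_measured")
    }
    tibble::tibble(
      cohort_id = id,
      dilution_variable = p$dilution_variable,
      time_of_day_adjusted = isTRUE(p$time_of_day_adjusted),
      analytes_measured = list(unlist(p$analytes_measured)),
      lod_per_analyte = list(lods)
    )
  })
  dplyr::bind_rows(rows)
}
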