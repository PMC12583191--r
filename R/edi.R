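#' Estimated daily intake from a urinary metabolite concentration
#'
#' Back-calculates the parent-compound daily intake (ug/kg body weight/day)
#' from a standardized urinary metabolite concentration:
#' \deqn{EDI = \frac{C_{adj} \cdot UV \cdot MW_{diester}}{FUE \cdot W \cdot
#'   MW_{metabolite}}}
#' where `C_adj` is the standardized concentration (ug/L), `UV` the average
#' daily urine volume (L/day; 1.6 L during pregnancy by default), `FUE` the
#' metabolite's molar fractional urinary excretion, `W` the body weight at
#' sampling (kg) and the MW ratio converts metabolite mass to parent mass.
#'
#' @param c_adj Standardized concentration, ug/L.
#' @param analyte Metabolite code (looked up in `registry`) or a one-row
#'   analyte definition.
#' @param weight Body weight at sampling, kg.
#' @param uv Daily urine volume, L/day.
#' @param registry Constants table from [analyte_registry()].
#' @return EDI in ug/kg/day (vectorized over `c_adj` and `weight`).
#' @export
#' @examples
#' compute_edi(50, "MnBP", weight = 70)
compute_edi <- function(c_adj, analyte, weight, uv = 1.6,
                        registry = analyte_registry()) {
  def <- if (is.character(analyte)) lookup_analyte(analyte, registry) else analyte
  if (!isTRUE(def$is_edi_eligible)) {
    stop("analyte '", def$metabolite_code,
         "' is not EDI-eligible; analyse its urinary concentration instead")
  }
  stopifnot(all(c_adj > 0), all(weight > 0), all(uv > 0))
  (c_adj * uv * def$mw_parent) / (def$fue * weight * def$mw_metabolite)
}

#' Aggregate metabolite measurements to a parent-compound exposure
#'
#' Combines the metabolites of one parent compound into a single exposure
#' value for a subject-sample:
#' * parents with several metabolites (DEHP) use the molar sum: the summed
#'   molar concentration is converted back to parent mass via the parent MW
#'   and divided by the summed FUE of the metabolites present, so metabolite
#'   subsets (panels lacking MEHP or MECPP) are handled consistently;
#' * single-metabolite parents reduce to [compute_edi()];
#' * non-eligible analytes (MCPP) pass through as concentrations.
#'
#' The di-butyl phthalate group (DBP) is the arithmetic sum of the DiBP and
#' DnBP daily intakes and is produced by [derive_exposures()].
#'
#' @param concentrations Named vector of standardized concentrations (ug/L)
#'   for metabolites of one parent.
#' @param parent_code Parent compound code.
#' @param weight Body weight at sampling, kg.
#' @param uv Daily urine volume, L/day.
#' @param registry Constants table.
#' @return Parent-level EDI (ug/kg/day), or concentration for non-eligible
#'   parents.
#' @export
aggregate_parent <- function(concentrations, parent_code, weight, uv = 1.6,
                             registry = analyte_registry()) {
  mets <- names(concentrations)
  if (length(mets) == 0) stop("empty metabolite set for parent ", parent_code)
  defs <- registry[match(mets, registry$metabolite_code), ]
  if (anyNA(defs$metabolite_code)) {
    stop("unknown metabolite(s): ",
         paste(mets[is.na(defs$metabolite_code)], collapse = ", "))
  }
  if (!all(defs$parent_code == parent_code)) {
    stop("metabolites do not all map to parent ", parent_code)
  }
  if (!all(defs$is_edi_eligible)) {
    if (length(mets) > 1) stop("non-EDI-eligible parent with several metabolites")
    return(unname(concentrations))
  }
  molar <- sum(concentrations / defs$mw_metabolite)   # umol/L
  mw_parent <- defs$mw_parent[1]
  fue <- sum(defs$fue)
  (molar * mw_parent * uv) / (fue * weight)
}

# IOM gestational weight-gain guideline, encoded as first-trimester total
# gain plus a BMI-category weekly rate thereafter (guideline midpoints).
iom_gain_table <- function() {
  tibble::tibble(
    bmi_category = c("underweight", "normal", "overweight", "obese"),
    bmi_lower = c(0, 18.5, 25, 30),
    bmi_upper = c(18.5, 25, 30, Inf),
    first_trimester_gain = 2.0,            # kg by week 13
    weekly_rate = c(0.51, 0.42, 0.28, 0.22) # kg/week after week 13
  )
}

#' Estimate maternal weight at a gestational week
#'
#' Adds the cumulative gestational weight gain recommended by the Institute
#' of Medicine to the pre-pregnancy weight: a fixed first-trimester total
#' (accrued linearly to week 13) plus a BMI-category-specific weekly rate
#' thereafter, using guideline midpoints. Monotone non-decreasing in
#' gestational week.
#'
#' @param pre_pregnancy_weight kg.
#' @param pre_pregnancy_bmi kg/m^2.
#' @param gestational_week Weeks, in \[0, 42\].
#' @return Estimated weight at sampling, kg (vectorized).
#' @export
estimate_weight_at_sampling <- function(pre_pregnancy_weight, pre_pregnancy_bmi,
                                        gestational_week) {
  stopifnot(all(pre_pregnancy_bmi > 0),
            all(gestational_week >= 0), all(gestational_week <= 42))
  tab <- iom_gain_table()
  idx <- findInterval(pre_pregnancy_bmi, tab$bmi_lower)
  rate <- tab$weekly_rate[idx]
  ft <- tab$first_trimester_gain[idx]
  gain <- ifelse(gestational_week <= 13,
                 ft * gestational_week / 13,
                 ft + rate * (gestational_week - 13))
  pre_pregnancy_weight + gain
}

# Normative daily urine output per kg body weight for young children,
# piecewise constant over age bands (L/kg/day).
child_uvw_table <- function() {
  tibble::tibble(
    age_lower = c(0, 1, 3),
    age_upper = c(1, 3, 6),
    uv_per_kg = c(0.040, 0.030, 0.025)
  )
}

#' Daily urine volume per kg body weight for a child
#'
#' Piecewise-constant lookup over age bands, from normative urine-output
#' values for young children. Multiplied by body weight this supplies the
#' `UV` term of the intake equation; equivalently `UV/W` can be used
#' directly when weight is unknown.
#'
#' @param age_years Child age in (0, 6).
#' @param table Override lookup table with columns `age_lower`, `age_upper`,
#'   `uv_per_kg`.
#' @return UV/W in L/kg/day (vectorized).
#' @export
child_uv_per_weight <- function(age_years, table = child_uvw_table()) {
  if (any(age_years <= 0 | age_years >= 6)) {
    stop("child age must lie in (0, 6) years")
  }
  idx <- findInterval(age_years, table$age_lower)
  table$uv_per_kg[idx]
}

#' Derive parent-compound exposures from standardized samples
#'
#' Maps a standardized urine-sample table (one metabolite measurement per
#' row) to one exposure record per subject, sampling time and parent
#' compound: metabolites are aggregated per [aggregate_parent()], DiBP and
#' DnBP intakes are summed into DBP, MCPP is carried on the concentration
#' scale, and the log2 analysis scale is attached.
#'
#' @param samples Standardized samples with `subject_id`, `cohort_id`,
#'   `sampling_time`, `analyte`, `concentration`, and a `weight` column
#'   (kg at sampling; ignored for concentration-scale analytes).
#' @param period `"prenatal"` (UV = 1.6 L/day) or `"postnatal"` (UV from
#'   [child_uv_per_weight()] with `sampling_time` as age, applied per kg).
#' @param registry Constants table.
#' @return A tibble of exposure records: `subject_id`, `cohort_id`,
#'   `parent_code`, `period`, `timing`, `value`, `scale`, `log2_value`.
#' @export
derive_exposures <- function(samples, period = c("prenatal", "postnatal"),
                             registry = analyte_registry()) {
  period <- match.arg(period)
  stopifnot(all(c("subject_id", "sampling_time", "analyte", "concentration",
                  "weight") %in% names(samples)))
  samples$parent_code <- registry$parent_code[
    match(samples$analyte, registry$metabolite_code)]
  if (anyNA(samples$parent_code)) {
    stop("unregistered analyte(s): ",
         paste(unique(samples$analyte[is.na(samples$parent_code)]), collapse = ", "))
  }
  if (!"cohort_id" %in% names(samples)) samples$cohort_id <- "pooled"
  rec <- samples |>
    dplyr::group_by(.data$subject_id, .data$cohort_id, .data$sampling_time,
                    .data$parent_code) |>
    dplyr::group_modify(function(d, key) {
      conc <- stats::setNames(d$concentration, d$analyte)
      w <- d$weight[1]
      uv <- if (period == "prenatal") 1.6 else
        child_uv_per_weight(key$sampling_time) * w
      val <- aggregate_parent(conc, key$parent_code, weight = w, uv = uv,
                              registry = registry)
      eligible <- registry$is_edi_eligible[
        registry$metabolite_code == d$analyte[1]]
      tibble::tibble(value = val,
                     scale = if (isTRUE(eligible)) "edi" else "concentration")
    }) |>
    dplyr::ungroup()
  # DBP = DiBP + DnBP daily intakes
  dbp <- rec |>
    dplyr::filter(.data$parent_code %in% c("DiBP", "DnBP")) |>
    dplyr::group_by(.data$subject_id, .data$cohort_id, .data$sampling_time) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(parent_code = "DBP", value = sum(.data$value),
                     scale = "edi", .groups = "drop")
  out <- dplyr::bind_rows(rec, dbp) |>
    dplyr::transmute(.data$subject_id, .data$cohort_id,
                     parent_code = .data$parent_code, period = period,
                     timing = .data$sampling_time, value = .data$value,
                     scale = .data$scale, log2_value = log2(.data$value)) |>
    dplyr::arrange(.data$subject_id, .data$parent_code, .data$timing)
  tibble::as_tibble(out)
}

#' Average prenatal exposures per subject
#'
#' When a subject has several prenatal samples, the analysis exposure is
#' their arithmetic mean on the natural scale, log2-transformed afterwards
#' (averaging log values would target a different estimand). Postnatal
#' records are analysed per timepoint and are returned unchanged.
#'
#' @param exposures Exposure records from [derive_exposures()].
#' @return One record per subject and compound (prenatal), or the input
#'   (postnatal).
#' @export
period_average <- function(exposures) {
  if (all(exposures$period == "postnatal")) return(exposures)
  pre <- exposures[exposures$period == "prenatal", ]
  post <- exposures[exposures$period == "postnatal", ]
  avg <- pre |>
    dplyr::group_by(.data$subject_id, .data$cohort_id, .data$parent_code,
                    .data$period, .data$scale) |>
    dplyr::summarise(timing = mean(.data$timing), value = mean(.data$value),
                     .groups = "drop") |>
    dplyr::mutate(log2_value = log2(.data$value))
  tibble::as_tibble(dplyr::bind_rows(avg, post))
}

#' Average prenatal exposures within trimesters
#'
#' Samples are binned by gestational week into trimesters (default
#' boundaries: first < 14 weeks, second 14-27, third >= 28, the obstetric
#' convention) and averaged within each bin on the natural scale. Subjects
#' without a sample in a trimester are absent from that trimester's output.
#'
#' @param exposures Prenatal exposure records (timing in gestational weeks).
#' @param boundaries Two cut points (start of trimester 2 and 3).
#' @return A tibble with a `trimester` column (1, 2, 3) and one record per
#'   subject, compound and trimester.
#' @export
trimester_average <- function(exposures, boundaries = c(14, 28)) {
  stopifnot(length(boundaries) == 2, diff(boundaries) > 0)
  out <- exposures |>
    dplyr::mutate(trimester = findInterval(.data$timing, boundaries) + 1L) |>
    dplyr::group_by(.data$subject_id, .data$cohort_id, .data$parent_code,
                    .data$period, .data$scale, .data$trimester) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(log2_value = log2(.data$value))
  tibble::as_tibble(out)
}
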