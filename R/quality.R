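#' Practice-level data-quality screening
#'
#' Before any morbidity analysis, practices must show sufficient recording
#' quality over the whole study period. A practice is eligible when it has
#' (1) at least 500 listed patients, (2) complete morbidity registration,
#' operationalised as 46 or more recorded weeks in every study year (a year
#' minus at most six weeks of holidays), and (3) sufficient diagnostic
#' coding, at least 70% of recorded encounters carrying an ICPC code
#' (computed over the whole period). All three thresholds are inclusive.
#'
#' A "recorded week" is an ISO-8601 week containing at least one encounter
#' of any kind. A practice without any encounter in a study year is
#' ineligible with reason `"no registration"`.
#'
#' @param patients Patients table (`patient_id`, `practice_id`, ...).
#' @param encounters Encounters table; `icpc` may be `NA` for uncoded
#'   encounters.
#' @param years Integer vector of study years that must each be covered.
#' @param min_patients,min_weeks,min_coded_fraction Inclusive thresholds.
#' @return A tibble with one row per practice: `practice_id`,
#'   `listed_patients`, `min_recorded_weeks` (worst year),
#'   `icpc_coded_fraction`, `eligible`, `reason` (`NA` when eligible).
#' @export
evaluate_practices <- function(patients, encounters, years,
                               min_patients = 500L, min_weeks = 46L,
                               min_coded_fraction = 0.70) {
  stopifnot(length(years) >= 1)
  enc <- dplyr::left_join(encounters,
                          patients[, c("patient_id", "practice_id")],
                          by = "patient_id")
  enc$year <- as.integer(format(enc$date, "%G"))  # ISO week-year
  enc$week <- format(enc$date, "%G-W%V")

  listed <- dplyr::count(patients, .data$practice_id, name = "listed_patients")

  weeks <- enc |>
    dplyr::filter(.data$year %in% years) |>
    dplyr::distinct(.data$practice_id, .data$year, .data$week) |>
    dplyr::count(.data$practice_id, .data$year, name = "recorded_weeks") |>
    tidyr::complete(practice_id = listed$practice_id, year = years,
                    fill = list(recorded_weeks = 0L))

  worst <- weeks |>
    dplyr::group_by(.data$practice_id) |>
    dplyr::summarise(min_recorded_weeks = min(.data$recorded_weeks),
                     any_empty_year = any(.data$recorded_weeks == 0L))

  coded <- enc |>
    dplyr::group_by(.data$practice_id) |>
    dplyr::summarise(icpc_coded_fraction =
                       ifelse(dplyr::n() == 0, NA_real_,
                              mean(!is.na(.data$icpc))))

  rep <- listed |>
    dplyr::left_join(worst, by = "practice_id") |>
    dplyr::left_join(coded, by = "practice_id")
  rep$min_recorded_weeks[is.na(rep$min_recorded_weeks)] <- 0L
  rep$any_empty_year[is.na(rep$any_empty_year)] <- TRUE

  rep$eligible <- rep$listed_patients >= min_patients &
    rep$min_recorded_weeks >= min_weeks &
    !is.na(rep$icpc_coded_fraction) &
    rep$icpc_coded_fraction >= min_coded_fraction

  rep$reason <- dplyr::case_when(
    rep$eligible ~ NA_character_,
    rep$any_empty_year ~ "no registration",
    rep$listed_patients < min_patients ~ "too few listed patients",
    rep$min_recorded_weeks < min_weeks ~ "incomplete registration weeks",
    TRUE ~ "insufficient ICPC coding"
  )
  rep$any_empty_year <- NULL
  rep
}
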