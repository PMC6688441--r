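year_start <- function(year) as.Date(sprintf("%d-01-01", year))
year_end <- function(year) as.Date(sprintf("%d-12-31", year))

# inclusive overlap in days of [s1,e1] and [s2,e2]; 0 when disjoint
overlap_days <- function(s1, e1, s2, e2) {
  d <- as.numeric(pmin(e1, e2) - pmax(s1, s2)) + 1
  pmax(d, 0)
}

#' At-risk person-years for one diagnosis code
#'
#' The incidence denominator for long-lasting and chronic diseases is the
#' person-time actually at risk: the total person-years of the population
#' minus the time spent inside episodes of illness of the code during the
#' target year. Episode time is clipped to the year and to the patient's
#' observation windows before subtraction.
#'
#' @param total_py Total person-years in the target year
#'   (see [person_years()]).
#' @param episodes Episodes of one code, from [build_episodes()].
#' @param windows Observation windows.
#' @param year Target calendar year.
#' @return At-risk person-years (non-negative; negative results indicate an
#'   invariant violation and raise an error).
#' @export
at_risk_person_years <- function(total_py, episodes, windows, year) {
  if (nrow(episodes) == 0) return(total_py)
  joined <- dplyr::inner_join(
    episodes[, c("patient_id", "start_date", "stop_date")],
    windows, by = "patient_id", relationship = "many-to-many")
  joined$days <- overlap_days(
    pmax(joined$start_date, year_start(year)),
    pmin(joined$stop_date, year_end(year)),
    joined$start, joined$end)
  per_pat <- dplyr::summarise(dplyr::group_by(joined, .data$patient_id),
                              diseased_py = sum(.data$days) / 365.25,
                              .groups = "drop")
  # a patient can lose at most their own observed time in the year (the
  # day-count convention can otherwise overshoot by a fraction of a day in
  # leap years)
  obs <- patient_person_years(windows, year)
  per_pat <- dplyr::left_join(per_pat, obs, by = "patient_id")
  per_pat$diseased_py <- pmin(per_pat$diseased_py, per_pat$py)
  at_risk <- total_py - sum(per_pat$diseased_py)
  if (at_risk < -1e-9)
    stop("At-risk person-years negative (", signif(at_risk, 4),
         "); episode time exceeds observed person-time", call. = FALSE)
  max(at_risk, 0)
}

#' Incidence rate per 1000 person-years for one code and year
#'
#' The numerator counts episodes of illness whose start date falls inside
#' the target year; one patient can contribute several acute episodes.
#' Chronic episodes that started before the year (in particular pre-study
#' diagnoses) are never incident. The denominator is the total population
#' person-years for acute categories, and the at-risk person-years for
#' long-lasting and chronic diseases (disease duration is not subtracted
#' for acute codes: the at-risk period is nearly the whole population time,
#' and patients can remain at risk during an active episode).
#'
#' @param episodes Episode tibble (may contain several codes; filtered).
#' @param code ICPC-1 code.
#' @param year Target calendar year.
#' @param total_py Total person-years in the year.
#' @param at_risk_py At-risk person-years; required for `long_lasting` and
#'   `chronic` codes.
#' @param catalog An `icpc_catalog` (for the category / denominator rule).
#' @return A single rate per 1000 person-years, or `NA` (with a warning)
#'   when the denominator is zero.
#' @export
incidence_rate <- function(episodes, code, year, total_py,
                           at_risk_py = NULL,
                           catalog = default_catalog()) {
  category <- lookup_category(catalog, code)$category
  ep <- episodes[episodes$icpc == code, ]
  n_new <- sum(ep$start_date >= year_start(year) &
                 ep$start_date <= year_end(year))
  denom <- if (category %in% c("long_lasting", "chronic")) {
    if (is.null(at_risk_py))
      stop("at_risk_py is required for ", category, " codes", call. = FALSE)
    at_risk_py
  } else {
    total_py
  }
  if (denom <= 0) {
    warning("Zero person-years denominator for ", code, " in ", year,
            "; incidence undefined", call. = FALSE)
    return(NA_real_)
  }
  1000 * n_new / denom
}

#' Prevalence rate per 1000 person-years for one code and year
#'
#' The numerator counts distinct persons with at least one episode of
#' illness of the code overlapping the target year (ongoing or newly
#' started); the denominator is always the total population person-years.
#'
#' @inheritParams incidence_rate
#' @return A single rate per 1000 person-years, or `NA` (with a warning)
#'   when the denominator is zero.
#' @export
prevalence_rate <- function(episodes, code, year, total_py) {
  ep <- episodes[episodes$icpc == code, ]
  active <- ep$stop_date >= year_start(year) & ep$start_date <= year_end(year)
  n_persons <- dplyr::n_distinct(ep$patient_id[active])
  if (total_py <= 0) {
    warning("Zero person-years denominator for ", code, " in ", year,
            "; prevalence undefined", call. = FALSE)
    return(NA_real_)
  }
  1000 * n_persons / total_py
}

#' Per-code episode counts and durations for one calendar year
#'
#' Selects episodes of illness active in the target year — stop date after
#' December 31 of the prior year and start date within or before the year —
#' and reports, per code, their number and the mean duration in days,
#' counting only the days falling inside the year.
#'
#' @param episodes Episode tibble from [build_episodes()].
#' @param year Target calendar year.
#' @return Tibble: `icpc`, `n_episodes`, `mean_duration_days`.
#' @export
episode_summary <- function(episodes, year) {
  sel <- episodes$stop_date > year_end(year - 1) &
    episodes$start_date <= year_end(year)
  ep <- episodes[sel, ]
  if (nrow(ep) == 0)
    return(tibble::tibble(icpc = character(), n_episodes = integer(),
                          mean_duration_days = numeric()))
  ep$days_in_year <- overlap_days(ep$start_date, ep$stop_date,
                                  year_start(year), year_end(year))
  ep |>
    dplyr::group_by(icpc = .data$icpc) |>
    dplyr::summarise(n_episodes = dplyr::n(),
                     mean_duration_days = mean(.data$days_in_year))
}

#' Incidence and prevalence per 1000 person-years for all (or given) codes
#'
#' Convenience wrapper computing, per code, the incident episode count, the
#' prevalent person count, the total and at-risk person-years, and both
#' rates for one calendar year, applying the per-category denominator rule
#' of [incidence_rate()].
#'
#' @param episodes Episode tibble from [build_episodes()].
#' @param windows Observation windows of the study population.
#' @param year Target calendar year.
#' @param catalog An `icpc_catalog`.
#' @param codes Codes to report; default all codes present in `episodes`.
#' @return Tibble: `icpc`, `year`, `category`, `cfi_days`,
#'   `incident_episodes`, `prevalent_persons`, `total_py`, `at_risk_py`,
#'   `incidence_per_1000py`, `prevalence_per_1000py`, `denominator_used`.
#' @export
morbidity_rates <- function(episodes, windows, year,
                            catalog = default_catalog(), codes = NULL) {
  if (is.null(codes)) codes <- sort(unique(episodes$icpc))
  total_py <- person_years(windows, year)
  rows <- lapply(codes, function(code) {
    cat_row <- lookup_category(catalog, code)
    ep <- episodes[episodes$icpc == code, ]
    arpy <- at_risk_person_years(total_py, ep, windows, year)
    active <- ep$stop_date >= year_start(year) &
      ep$start_date <= year_end(year)
    tibble::tibble(
      icpc = code, year = as.integer(year),
      category = cat_row$category, cfi_days = cat_row$cfi_days,
      incident_episodes = sum(ep$start_date >= year_start(year) &
                                ep$start_date <= year_end(year)),
      prevalent_persons = dplyr::n_distinct(ep$patient_id[active]),
      total_py = total_py, at_risk_py = arpy,
      incidence_per_1000py = incidence_rate(ep, code, year, total_py,
                                            at_risk_py = arpy,
                                            catalog = catalog),
      prevalence_per_1000py = prevalence_rate(ep, code, year, total_py),
      denominator_used = ifelse(cat_row$category %in%
                                  c("long_lasting", "chronic"),
                                "at_risk", "total")
    )
  })
  dplyr::bind_rows(rows)
}

# episode construction for one code under an arbitrary interval length
build_with_cfi <- function(contacts_code, cfi, windows) {
  half <- floor(cfi / 2)
  win_by_pat <- split(windows[, c("start", "end")], windows$patient_id)
  groups <- split(contacts_code$date, contacts_code$patient_id)
  out <- lapply(names(groups), function(pid) {
    runs <- split_contacts(groups[[pid]], cfi)
    w <- win_by_pat[[pid]]
    dplyr::bind_rows(lapply(runs, function(run) {
      last <- max(run)
      obs_end <- as.Date(NA)
      if (!is.null(w) && nrow(w) > 0) {
        inside <- w$start <= last & last <= w$end
        obs_end <- if (any(inside)) w$end[which(inside)[1]] else max(w$end)
      }
      stop_date <- last + half
      censored <- FALSE
      if (!is.na(obs_end) && stop_date > obs_end) {
        stop_date <- max(obs_end, last)
        censored <- TRUE
      }
      tibble::tibble(patient_id = pid, start_date = min(run),
                     stop_date = stop_date, n_contacts = length(run),
                     censored = censored)
    }))
  })
  res <- dplyr::bind_rows(out)
  res$icpc <- contacts_code$icpc[1]
  res
}

#' Sensitivity of rates to the contact-free interval length
#'
#' Rebuilds the episodes of illness of one non-chronic code under each of a
#' set of contact-free interval lengths and reports the resulting incidence
#' and prevalence rates. Lengthening the interval merges more contacts into
#' one episode, so incidence falls while prevalence rises (longer episodes
#' reach into the target year from earlier years).
#'
#' @param contacts Cleaned contact tibble (all codes; filtered internally).
#' @param code Non-chronic ICPC-1 code to sweep.
#' @param windows Observation windows.
#' @param year Target calendar year.
#' @param cfi_days_grid Interval lengths in days to test.
#' @param catalog An `icpc_catalog` (denominator rule only; the swept
#'   interval overrides the catalog interval).
#' @return Tibble with one row per interval: `icpc`, `year`, `cfi_days`,
#'   `incident_episodes`, `prevalent_persons`, `total_py`, `at_risk_py`,
#'   `incidence_per_1000py`, `prevalence_per_1000py`.
#' @export
cfi_sweep <- function(contacts, code, windows, year,
                      cfi_days_grid = c(28L, 56L, 112L),
                      catalog = default_catalog()) {
  cat_row <- lookup_category(catalog, code)
  if (cat_row$category == "chronic")
    stop("cfi_sweep is undefined for chronic codes (", code,
         "): no contact-free interval applies", call. = FALSE)
  cc <- contacts[contacts$icpc == code, ]
  cc <- dplyr::distinct(dplyr::arrange(cc, .data$patient_id, .data$date),
                        .data$patient_id, .data$date, .keep_all = TRUE)
  total_py <- person_years(windows, year)
  at_risk_cat <- cat_row$category %in% c("long_lasting", "chronic")

  rows <- lapply(cfi_days_grid, function(cfi) {
    ep <- build_with_cfi(cc, cfi, windows)
    arpy <- at_risk_person_years(total_py, ep, windows, year)
    active <- ep$stop_date >= year_start(year) &
      ep$start_date <= year_end(year)
    denom <- if (at_risk_cat) arpy else total_py
    n_new <- sum(ep$start_date >= year_start(year) &
                   ep$start_date <= year_end(year))
    n_prev <- dplyr::n_distinct(ep$patient_id[active])
    tibble::tibble(
      icpc = code, year = as.integer(year), cfi_days = as.integer(cfi),
      incident_episodes = n_new, prevalent_persons = n_prev,
      total_py = total_py, at_risk_py = arpy,
      incidence_per_1000py = if (denom > 0) 1000 * n_new / denom
                             else NA_real_,
      prevalence_per_1000py = if (total_py > 0) 1000 * n_prev / total_py
                              else NA_real_
    )
  })
  res <- dplyr::bind_rows(rows)
  res <- res[order(res$cfi_days), ]
  if (any(diff(res$incidence_per_1000py) > 1e-9, na.rm = TRUE))
    warning("Incidence increased as the interval grew", call. = FALSE)
  if (any(diff(res$prevalence_per_1000py) < -1e-9, na.rm = TRUE))
    warning("Prevalence decreased as the interval grew", call. = FALSE)
  res
}
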