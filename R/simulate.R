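#' Default per-code simulation settings
#'
#' One row per simulated ICPC-1 code: the disease category, the annual
#' hazard of starting a new true episode (per person-year), the gamma
#' true-duration distribution in days, and the expected number of follow-up
#' contacts within an episode (for chronic codes: management contacts per
#' year). `p_prior` is the probability that a patient enters the study with
#' a pre-existing chronic diagnosis (chronic codes only). Hazards and
#' durations are plausible general-practice magnitudes for each category:
#' frequent short respiratory infections, less frequent moderate/long acute
#' problems, sporadic long-lasting disease, and a chronic disease with a
#' realistic standing prevalence.
#'
#' @return A tibble usable as the `codes` argument of [sim_config()].
#' @export
sim_codes <- function() {
  tibble::tibble(
    icpc = c("R74", "U71", "P06", "S88", "T90"),
    category = c("acute_short", "acute_moderate", "acute_long",
                 "long_lasting", "chronic"),
    annual_hazard = c(0.40, 0.20, 0.08, 0.08, 0.01),
    duration_shape = c(2, 2, 2, 2, NA),
    duration_scale = c(5, 10, 25, 60, NA),
    contacts_mean = c(1.0, 1.5, 2.0, 2.0, 2.0),
    p_prior = c(0, 0, 0, 0, 0.05)
  )
}

#' Build and validate a simulation configuration
#'
#' The generator emulates a small general-practice registry over a
#' multi-year horizon with the recording imperfections seen in routine
#' data: episodes of care left open or closed automatically
#' (`p_open_ended_eoc`), several episodes of care opened for one disease
#' (`p_duplicate_eoc`), disease encounters attached to the episode of care
#' of another disease while keeping their own code (`p_miscode`), contacts
#' recorded loose outside any episode of care (`p_single_encounter`), and
#' quarterly registration churn (`p_drop_quarter`). Degradations are
#' applied after the ground truth is fixed, so truth tables are unaffected.
#'
#' In `separable` mode, true episode durations are capped at one day less
#' than the code's contact-free interval and consecutive true episodes are
#' at least `cfi + half-interval` days apart, so the episode construction
#' algorithm can recover the truth exactly; a `min_gap_days` below that
#' bound is a configuration error.
#'
#' @param seed Integer RNG seed; the entire simulation is reproducible
#'   from it.
#' @param n_practices,patients_per_practice Population size.
#' @param horizon_start,horizon_end Study horizon (ISO dates).
#' @param codes Per-code settings, see [sim_codes()].
#' @param p_open_ended_eoc,p_duplicate_eoc,p_miscode,p_single_encounter,p_drop_quarter
#'   Degradation probabilities in `[0, 1]`.
#' @param p_death Probability a patient dies during the horizon.
#' @param prescription_fraction Fraction of recorded contacts that are
#'   diagnosis-coded prescriptions rather than consultations.
#' @param separable Enforce exactly recoverable episode spacing (see above).
#' @param min_gap_days Minimum gap between a true episode's resolution and
#'   the next onset, per code; default `cfi + half + 1` in separable mode,
#'   `1` otherwise.
#' @return A validated config list for [simulate_ehr()].
#' @export
sim_config <- function(seed = 1L,
                       n_practices = 2L,
                       patients_per_practice = 50L,
                       horizon_start = "2010-01-01",
                       horizon_end = "2012-12-31",
                       codes = sim_codes(),
                       p_open_ended_eoc = 0.7,
                       p_duplicate_eoc = 0.1,
                       p_miscode = 0.05,
                       p_single_encounter = 0.05,
                       p_drop_quarter = 0.02,
                       p_death = 0.01,
                       prescription_fraction = 0.3,
                       separable = TRUE,
                       min_gap_days = NULL) {
  probs <- c(p_open_ended_eoc = p_open_ended_eoc,
             p_duplicate_eoc = p_duplicate_eoc, p_miscode = p_miscode,
             p_single_encounter = p_single_encounter,
             p_drop_quarter = p_drop_quarter, p_death = p_death,
             prescription_fraction = prescription_fraction)
  if (any(probs < 0 | probs > 1))
    stop("Degradation probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  if (any(codes$annual_hazard < 0))
    stop("Annual hazards must be non-negative", call. = FALSE)
  stopifnot(all(codes$category %in% DISEASE_CATEGORY_NAMES))

  cfi <- cfi_days(codes$category)
  half <- half_interval_days(codes$category)
  floor_gap <- ifelse(is.na(cfi), 1, cfi + half)
  if (is.null(min_gap_days)) {
    min_gap_days <- if (separable) ifelse(is.na(cfi), 1, cfi + half + 1) else
      rep(1, nrow(codes))
  }
  min_gap_days <- rep_len(min_gap_days, nrow(codes))
  if (separable && any(!is.na(cfi) & min_gap_days < floor_gap))
    stop("separable mode requires min_gap_days >= cfi + half-interval for ",
         "code(s): ",
         paste(codes$icpc[!is.na(cfi) & min_gap_days < floor_gap],
               collapse = ", "), call. = FALSE)
  codes$min_gap_days <- min_gap_days

  list(seed = as.integer(seed), n_practices = as.integer(n_practices),
       patients_per_practice = as.integer(patients_per_practice),
       horizon_start = as.Date(horizon_start),
       horizon_end = as.Date(horizon_end),
       codes = codes,
       p_open_ended_eoc = p_open_ended_eoc,
       p_duplicate_eoc = p_duplicate_eoc,
       p_miscode = p_miscode,
       p_single_encounter = p_single_encounter,
       p_drop_quarter = p_drop_quarter,
       p_death = p_death,
       prescription_fraction = prescription_fraction,
       separable = separable)
}

# true episode stream for one patient and one non-chronic code
sim_true_episodes_one <- function(pid, code_row, h_start, h_end, separable) {
  cfi <- cfi_days(code_row$category)
  rate <- code_row$annual_hazard / 365.25
  if (rate <= 0) return(NULL)
  eps <- list()
  t <- as.numeric(h_start) + rexp(1, rate)
  while (t <= as.numeric(h_end)) {
    onset <- as.Date(floor(t), origin = "1970-01-01")
    dur <- rgamma(1, shape = code_row$duration_shape,
                  scale = code_row$duration_scale)
    if (separable) dur <- min(dur, cfi - 1)
    dur <- max(round(dur), 0)
    resolution <- onset + dur
    n_extra <- rpois(1, code_row$contacts_mean)
    extra <- if (n_extra > 0 && dur > 0)
      onset + sort(unique(round(runif(n_extra, 0, dur)))) else NULL
    contact_dates <- sort(unique(c(onset, extra)))
    contact_dates <- contact_dates[contact_dates <= h_end]
    eps[[length(eps) + 1]] <-
      list(onset = onset, resolution = resolution,
           contact_dates = contact_dates)
    t <- as.numeric(resolution) + code_row$min_gap_days + rexp(1, rate)
  }
  eps
}

# one chronic disease history for one patient
sim_chronic_one <- function(pid, code_row, h_start, h_end) {
  u_prior <- runif(1)
  years <- as.numeric(h_end - h_start + 1) / 365.25
  if (u_prior < code_row$p_prior) {
    onset <- h_start - 1 - round(runif(1, 0, 3650))  # up to ~10y before
    prior <- TRUE
  } else {
    t <- as.numeric(h_start) + rexp(1, max(code_row$annual_hazard, 1e-12) /
                                      365.25)
    if (t > as.numeric(h_end)) return(NULL)
    onset <- as.Date(floor(t), origin = "1970-01-01")
    prior <- FALSE
  }
  obs_from <- max(onset, h_start)
  obs_years <- as.numeric(h_end - obs_from + 1) / 365.25
  n_manage <- rpois(1, code_row$contacts_mean * obs_years)
  manage <- if (n_manage > 0)
    obs_from + sort(unique(round(runif(n_manage, 0,
                                       as.numeric(h_end - obs_from)))))
    else NULL
  contact_dates <- if (prior) manage else c(onset, manage)
  if (is.null(contact_dates)) contact_dates <- as.Date(character())
  list(onset = onset, resolution = as.Date(NA), prior = prior,
       contact_dates = sort(unique(contact_dates)))
}

#' Simulate a synthetic primary-care EHR extract with ground truth
#'
#' Generates the five raw input tables (patients, quarterly registrations,
#' encounters, episodes of care, chronic diagnoses) plus the underlying
#' ground truth, fully reproducibly from the config seed. Degradation
#' random draws are made unconditionally, so changing one degradation
#' probability never perturbs any other part of the simulation — setting
#' `p_open_ended_eoc` from 0 to 1 changes only recorded stop dates.
#'
#' @param config A configuration from [sim_config()].
#' @return A list with `tables` (named list of the five tibbles, passing
#'   [validate_ehr()]) and `truth`: `episodes` (one row per true episode:
#'   `true_episode_id`, `patient_id`, `icpc`, `category`, `onset`,
#'   `resolution` — `NA` for ongoing chronic disease — and `n_contacts`),
#'   `contacts` (every true contact with its episode id), `encounter_map`
#'   (recorded encounter id to true episode id), `n_miscoded` (number of
#'   injected detectable miscodings), and the `config`.
#' @export
simulate_ehr <- function(config = sim_config()) {
  set.seed(config$seed)
  h_start <- config$horizon_start
  h_end <- config$horizon_end
  codes <- config$codes

  ## -- population ----------------------------------------------------------
  n_pat <- config$n_practices * config$patients_per_practice
  patients <- tibble::tibble(
    patient_id = sprintf("p%04d", seq_len(n_pat)),
    practice_id = sprintf("gp%02d", rep(seq_len(config$n_practices),
                                        each = config$patients_per_practice)),
    death_date = as.Date(NA)
  )
  u_death <- runif(n_pat)
  death_day <- round(runif(n_pat, 0, as.numeric(h_end - h_start)))
  dies <- u_death < config$p_death
  patients$death_date[dies] <- h_start + death_day[dies]

  ## -- registration (quarterly claims) -------------------------------------
  y0 <- as.integer(format(h_start, "%Y")); y1 <- as.integer(format(h_end, "%Y"))
  qgrid <- tidyr::expand_grid(year = y0:y1, quarter = 1:4)
  qgrid <- qgrid[quarter_start(qgrid$year, qgrid$quarter) >= h_start &
                   quarter_end(qgrid$year, qgrid$quarter) <= h_end, ]
  reg <- tidyr::expand_grid(patient_id = patients$patient_id,
                            qgrid)
  u_reg <- runif(nrow(reg))
  keep <- u_reg >= config$p_drop_quarter
  dd <- patients$death_date[match(reg$patient_id, patients$patient_id)]
  keep <- keep & (is.na(dd) | quarter_start(reg$year, reg$quarter) <= dd)
  registrations <- reg[keep, c("patient_id", "year", "quarter")]

  ## -- ground truth --------------------------------------------------------
  truth_eps <- list()
  truth_contacts <- list()
  chronic_rows <- list()
  eid <- 0L
  for (p in seq_len(n_pat)) {
    pid <- patients$patient_id[p]
    death <- patients$death_date[p]
    for (k in seq_len(nrow(codes))) {
      cr <- codes[k, ]
      if (cr$category == "chronic") {
        ep <- sim_chronic_one(pid, cr, h_start, h_end)
        eps <- if (is.null(ep)) list() else list(ep)
      } else {
        eps <- sim_true_episodes_one(pid, cr, h_start, h_end,
                                     config$separable)
        if (is.null(eps)) eps <- list()
      }
      for (ep in eps) {
        cdates <- ep$contact_dates
        if (!is.na(death)) cdates <- cdates[cdates <= death]
        is_prior <- isTRUE(ep$prior)
        if (!is.na(death) && ep$onset > death) next
        if (length(cdates) == 0 && !is_prior) next
        eid <- eid + 1L
        id <- sprintf("te%05d", eid)
        res <- ep$resolution
        if (!is.na(death) && !is.na(res)) res <- min(res, death)
        truth_eps[[eid]] <- tibble::tibble(
          true_episode_id = id, patient_id = pid, icpc = cr$icpc,
          category = cr$category, onset = ep$onset, resolution = res,
          prior_diagnosis = is_prior, n_contacts = length(cdates))
        if (length(cdates) > 0)
          truth_contacts[[eid]] <- tibble::tibble(
            true_episode_id = id, patient_id = pid, icpc = cr$icpc,
            date = cdates)
        if (is_prior)
          chronic_rows[[eid]] <- tibble::tibble(
            patient_id = pid, icpc = cr$icpc, diagnosis_date = ep$onset)
      }
    }
  }
  truth_episodes <- dplyr::bind_rows(truth_eps)
  truth_contact_tbl <- dplyr::bind_rows(truth_contacts)
  chronic_diagnoses <- dplyr::bind_rows(chronic_rows)
  if (nrow(chronic_diagnoses) == 0)
    chronic_diagnoses <- tibble::tibble(patient_id = character(),
                                        icpc = character(),
                                        diagnosis_date = as.Date(character()))

  ## -- recording + degradation --------------------------------------------
  n_ep <- nrow(truth_episodes)
  u_single <- runif(max(n_ep, 1))
  u_open <- runif(max(n_ep, 1))
  u_dup <- runif(max(n_ep, 1))
  u_dupfrac <- runif(max(n_ep, 1))

  eoc_rows <- list()
  enc_rows <- list()
  enc_map <- list()
  eoc_n <- 0L
  enc_n <- 0L
  contacts_by_ep <- if (nrow(truth_contact_tbl) > 0)
    split(truth_contact_tbl$date, truth_contact_tbl$true_episode_id) else
    list()
  for (i in seq_len(n_ep)) {
    te <- truth_episodes[i, ]
    cdates <- contacts_by_ep[[te$true_episode_id]]
    if (is.null(cdates)) cdates <- as.Date(character())
    if (length(cdates) == 0) next  # prior chronic with no in-horizon contact
    as_single <- u_single[i] < config$p_single_encounter

    if (as_single) {
      host <- rep(NA_character_, length(cdates))
    } else if (te$category != "chronic" &&
               u_dup[i] < config$p_duplicate_eoc && length(cdates) >= 2) {
      # GP opened a second episode of care for the same problem
      kcut <- 1L + floor(u_dupfrac[i] * (length(cdates) - 1L))
      ids <- sprintf("eoc%05d", eoc_n + 1:2)
      open1 <- u_open[i] < config$p_open_ended_eoc
      eoc_rows[[length(eoc_rows) + 1]] <- tibble::tibble(
        episode_of_care_id = ids,
        patient_id = te$patient_id, icpc = te$icpc,
        recorded_start_date = c(cdates[1], cdates[kcut + 1L]),
        recorded_stop_date = if (open1) as.Date(c(NA, NA)) else
          c(cdates[kcut], te$resolution))
      eoc_n <- eoc_n + 2L
      host <- rep(ids, c(kcut, length(cdates) - kcut))
    } else {
      eoc_n <- eoc_n + 1L
      id <- sprintf("eoc%05d", eoc_n)
      open1 <- u_open[i] < config$p_open_ended_eoc
      stop_rec <- if (te$category == "chronic" || open1) as.Date(NA) else
        te$resolution
      eoc_rows[[length(eoc_rows) + 1]] <- tibble::tibble(
        episode_of_care_id = id, patient_id = te$patient_id, icpc = te$icpc,
        recorded_start_date = min(cdates), recorded_stop_date = stop_rec)
      host <- rep(id, length(cdates))
    }

    enc_ids <- sprintf("c%06d", enc_n + seq_along(cdates))
    enc_n <- enc_n + length(cdates)
    enc_rows[[length(enc_rows) + 1]] <- tibble::tibble(
      encounter_id = enc_ids, patient_id = te$patient_id, date = cdates,
      icpc = te$icpc, episode_of_care_id = host, source = "consultation")
    enc_map[[length(enc_map) + 1]] <- tibble::tibble(
      encounter_id = enc_ids, true_episode_id = te$true_episode_id)
  }
  encounters <- dplyr::bind_rows(enc_rows)
  episodes_of_care <- dplyr::bind_rows(eoc_rows)
  if (nrow(episodes_of_care) == 0)
    episodes_of_care <- tibble::tibble(episode_of_care_id = character(),
                                       patient_id = character(),
                                       icpc = character(),
                                       recorded_start_date = as.Date(character()),
                                       recorded_stop_date = as.Date(character()))
  if (nrow(encounters) == 0)
    encounters <- tibble::tibble(encounter_id = character(),
                                 patient_id = character(),
                                 date = as.Date(character()),
                                 icpc = character(),
                                 episode_of_care_id = character(),
                                 source = character())
  encounter_map <- dplyr::bind_rows(enc_map)

  n_enc <- nrow(encounters)
  u_rx <- runif(max(n_enc, 1))
  u_mis <- runif(max(n_enc, 1))
  u_host <- runif(max(n_enc, 1))

  if (n_enc > 0) {
    encounters$source[u_rx[seq_len(n_enc)] <
                        config$prescription_fraction] <- "prescription"

    # inject detectable miscodings: a disease-coded encounter filed under
    # another disease's episode of care, keeping its own code
    n_miscoded <- 0L
    eoc_disease <- episodes_of_care[
      icpc_kind(episodes_of_care$icpc) == "disease", ]
    eligible <- which(!is.na(encounters$episode_of_care_id) &
                        icpc_kind(encounters$icpc) == "disease" &
                        u_mis[seq_len(n_enc)] < config$p_miscode)
    for (j in eligible) {
      cand <- eoc_disease$episode_of_care_id[
        eoc_disease$patient_id == encounters$patient_id[j] &
          eoc_disease$icpc != encounters$icpc[j]]
      if (length(cand) == 0) next
      pick <- 1L + floor(u_host[j] * length(cand))
      encounters$episode_of_care_id[j] <- cand[pick]
      n_miscoded <- n_miscoded + 1L
    }
  } else {
    n_miscoded <- 0L
  }

  tables <- list(patients = patients, registrations = registrations,
                 encounters = encounters,
                 episodes_of_care = episodes_of_care,
                 chronic_diagnoses = chronic_diagnoses)
  validate_ehr(tables)
  list(tables = tables,
       truth = list(episodes = truth_episodes,
                    contacts = truth_contact_tbl,
                    encounter_map = encounter_map,
                    n_miscoded = n_miscoded,
                    config = config))
}

#' True incidence and prevalence rates from simulation ground truth
#'
#' Computed by direct counting on the true episodes: incidence counts true
#' onsets inside the year; prevalence counts distinct persons whose true
#' episode interval (onset to resolution; onset onward for ongoing chronic
#' disease) overlaps the year. Denominators follow the same per-category
#' rule as the pipeline (total person-years for acute codes, at-risk
#' person-years otherwise).
#'
#' @param truth The `truth` element of a [simulate_ehr()] result.
#' @param windows Observation windows of the simulated population.
#' @param year Target calendar year.
#' @return Tibble: `icpc`, `year`, `true_incident_episodes`,
#'   `true_prevalent_persons`, `total_py`,
#'   `true_incidence_per_1000py`, `true_prevalence_per_1000py`.
#' @export
truth_rates <- function(truth, windows, year) {
  te <- truth$episodes
  total_py <- person_years(windows, year)
  codes <- truth$config$codes
  rows <- lapply(seq_len(nrow(codes)), function(k) {
    cr <- codes[k, ]
    ep <- te[te$icpc == cr$icpc, ]
    stop_eff <- ep$resolution
    stop_eff[is.na(stop_eff)] <- year_end(year)  # ongoing chronic
    n_new <- sum(ep$onset >= year_start(year) & ep$onset <= year_end(year))
    active <- stop_eff >= year_start(year) & ep$onset <= year_end(year)
    n_prev <- dplyr::n_distinct(ep$patient_id[active])
    denom <- total_py
    if (cr$category %in% c("long_lasting", "chronic")) {
      ep2 <- tibble::tibble(patient_id = ep$patient_id,
                            start_date = ep$onset, stop_date = stop_eff)
      denom <- at_risk_person_years(total_py, ep2, windows, year)
    }
    tibble::tibble(
      icpc = cr$icpc, year = as.integer(year),
      true_incident_episodes = n_new, true_prevalent_persons = n_prev,
      total_py = total_py,
      true_incidence_per_1000py = if (denom > 0) 1000 * n_new / denom
                                  else NA_real_,
      true_prevalence_per_1000py = if (total_py > 0) 1000 * n_prev / total_py
                                   else NA_real_)
  })
  dplyr::bind_rows(rows)
}
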