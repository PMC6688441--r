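# fixtures are built in code; no data files

mk_windows <- function(patient_id = "p1", start = "2010-01-01",
                       end = "2012-12-31") {
  tibble::tibble(patient_id = patient_id, start = as.Date(start),
                 end = as.Date(end))
}

mk_contacts <- function(patient_id, dates, icpc,
                        origin = "single_encounter") {
  tibble::tibble(patient_id = patient_id, date = as.Date(dates),
                 icpc = icpc, origin = origin)
}

# the two-episode worked example: contacts at weeks 0, 1, 8 and 11,
# 4-week contact-free interval
worked_example_day0 <- as.Date("2012-01-02")
worked_example_contacts <- function(code = "R74", d0 = worked_example_day0) {
  mk_contacts("p1", d0 + 7 * c(0, 1, 8, 11), code)
}

empty_ehr_tables <- function() {
  list(
    patients = tibble::tibble(patient_id = character(),
                              practice_id = character(),
                              death_date = as.Date(character())),
    registrations = tibble::tibble(patient_id = character(),
                                   year = integer(), quarter = integer()),
    encounters = tibble::tibble(encounter_id = character(),
                                patient_id = character(),
                                date = as.Date(character()),
                                icpc = character(),
                                episode_of_care_id = character(),
                                source = character()),
    episodes_of_care = tibble::tibble(
      episode_of_care_id = character(), patient_id = character(),
      icpc = character(), recorded_start_date = as.Date(character()),
      recorded_stop_date = as.Date(character())),
    chronic_diagnoses = tibble::tibble(patient_id = character(),
                                       icpc = character(),
                                       diagnosis_date = as.Date(character()))
  )
}

# one patient, registered through 2012, with the worked-example encounters
worked_example_tables <- function(code = "R74", d0 = worked_example_day0) {
  t <- empty_ehr_tables()
  t$patients <- tibble::tibble(patient_id = "p1", practice_id = "gp1",
                               death_date = as.Date(NA))
  t$registrations <- tibble::tibble(patient_id = "p1", year = 2012L,
                                    quarter = 1:4)
  dates <- d0 + 7 * c(0, 1, 8, 11)
  t$encounters <- tibble::tibble(
    encounter_id = paste0("c", seq_along(dates)), patient_id = "p1",
    date = dates, icpc = code, episode_of_care_id = NA_character_,
    source = "consultation")
  t
}

# a fast, fully recoverable simulation configuration for property tests
clean_sim_config <- function(seed, n_patients = 15,
                             codes = sim_codes()[c(1, 4, 5), ]) {
  sim_config(seed = seed, n_practices = 1L,
             patients_per_practice = n_patients, codes = codes,
             p_open_ended_eoc = 0, p_duplicate_eoc = 0, p_miscode = 0,
             p_single_encounter = 0, p_drop_quarter = 0, p_death = 0,
             separable = TRUE)
}

run_pipeline <- function(sim, catalog = default_catalog()) {
  windows <- observation_windows(sim$tables$registrations,
                                 sim$tables$patients)
  merged <- merge_contacts(sim$tables$encounters,
                           sim$tables$episodes_of_care,
                           sim$tables$chronic_diagnoses, catalog)
  episodes <- build_episodes(merged$contacts, catalog, windows)
  list(windows = windows, merged = merged, episodes = episodes)
}
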