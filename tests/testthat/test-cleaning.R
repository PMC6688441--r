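mk_enc <- function(patient_id, dates, icpc, eoc = NA_character_,
                   source = "consultation", id_offset = 0L) {
  tibble::tibble(
    encounter_id = sprintf("c%03d", seq_along(dates) + id_offset),
    patient_id = patient_id, date = as.Date(dates), icpc = icpc,
    episode_of_care_id = eoc, source = source)
}

mk_eoc <- function(id, patient_id, icpc, start, stop = NA) {
  tibble::tibble(episode_of_care_id = id, patient_id = patient_id,
                 icpc = icpc, recorded_start_date = as.Date(start),
                 recorded_stop_date = as.Date(stop))
}

test_that("only foreign disease codes inside disease episodes are flagged", {
  expect_false(flag_incorrect("R05", "R96"))  # symptom within disease
  expect_true(flag_incorrect("K86", "T90"))   # two differing disease codes
  expect_false(flag_incorrect("R96", "R96"))  # identity
  expect_false(flag_incorrect("R74", "R05"))  # disease within symptom episode
})

test_that("within-episode encounters are recoded and the start date counts", {
  eoc <- mk_eoc("e1", "p1", "R96", "2012-01-10")
  enc <- mk_enc("p1", c("2012-01-10", "2012-02-01"), c("R05", "R96"),
                eoc = "e1")
  out <- merge_contacts(enc, eoc, empty_ehr_tables()$chronic_diagnoses)
  expect_equal(nrow(out$contacts), 3L)
  expect_true(all(out$contacts$icpc == "R96"))
  expect_setequal(out$contacts$origin,
                  c("episode_start", "within_episode_recoded"))
  expect_equal(sum(out$contacts$date == as.Date("2012-01-10")), 2L)
  expect_equal(out$audit$n_flagged, 0L)
})

test_that("miscoded encounters leave the host episode with their own code", {
  eoc <- mk_eoc("e1", "p1", "T90", "2012-01-05")
  enc <- mk_enc("p1", c("2012-01-05", "2012-03-01"), c("T90", "K86"),
                eoc = "e1")
  out <- merge_contacts(enc, eoc, empty_ehr_tables()$chronic_diagnoses)
  k86 <- out$contacts[out$contacts$icpc == "K86", ]
  expect_equal(k86$origin, "extracted_miscoded")
  expect_equal(k86$date, as.Date("2012-03-01"))
  expect_equal(sum(out$contacts$icpc == "T90"), 2L)  # encounter + start
  expect_equal(out$audit$n_flagged, 1L)
  expect_equal(out$audit$flagged_fraction, 1 / 2)
  expect_equal(out$audit$top_flagged_codes$icpc, "K86")
})

test_that("empty input gives an empty contact file and a zero audit", {
  t <- empty_ehr_tables()
  out <- merge_contacts(t$encounters, t$episodes_of_care,
                        t$chronic_diagnoses)
  expect_equal(nrow(out$contacts), 0L)
  expect_equal(out$audit$n_flagged, 0L)
  expect_true(all(out$audit$counts_by_origin == 0))
})

test_that("every coded input event yields exactly one contact", {
  eoc <- dplyr::bind_rows(mk_eoc("e1", "p1", "R96", "2012-01-10"),
                          mk_eoc("e2", "p1", "T90", "2012-02-01"))
  enc <- dplyr::bind_rows(
    mk_enc("p1", c("2012-01-10", "2012-01-20"), "R96", eoc = "e1"),
    mk_enc("p1", "2012-02-10", "K86", eoc = "e2", id_offset = 10L),
    mk_enc("p1", "2012-05-01", "R05", source = "prescription",
           id_offset = 20L),
    mk_enc("p1", "2012-06-01", NA_character_, id_offset = 30L))
  cd <- tibble::tibble(patient_id = "p1", icpc = "T90",
                       diagnosis_date = as.Date("2005-03-01"))
  out <- merge_contacts(enc, eoc, cd)
  # 4 coded encounters + 2 episode starts + 1 chronic diagnosis
  expect_equal(nrow(out$contacts), 7L)
  expect_equal(out$audit$n_uncoded_dropped, 1L)
  expect_equal(unname(out$audit$counts_by_origin["prescription"]), 1L)
  expect_equal(unname(out$audit$counts_by_origin["prior_chronic_diagnosis"]),
               1L)
  expect_equal(out$audit$flagged_fraction,
               out$audit$n_flagged / out$audit$n_coded_events)
})

test_that("re-merging the merged contacts changes nothing", {
  eoc <- mk_eoc("e1", "p1", "R96", "2012-01-10")
  enc <- dplyr::bind_rows(
    mk_enc("p1", c("2012-01-10", "2012-02-01"), c("R05", "R96"), eoc = "e1"),
    mk_enc("p1", "2012-03-01", "R74", id_offset = 10L))
  out1 <- merge_contacts(enc, eoc, empty_ehr_tables()$chronic_diagnoses)
  # feed the merged file back in as loose single encounters
  enc2 <- tibble::tibble(
    encounter_id = sprintf("c%03d", seq_len(nrow(out1$contacts))),
    patient_id = out1$contacts$patient_id, date = out1$contacts$date,
    icpc = out1$contacts$icpc, episode_of_care_id = NA_character_,
    source = "consultation")
  out2 <- merge_contacts(enc2, empty_ehr_tables()$episodes_of_care,
                         empty_ehr_tables()$chronic_diagnoses)
  cols <- c("patient_id", "date", "icpc")
  expect_equal(dedupe_contacts(out2$contacts)[cols],
               dedupe_contacts(out1$contacts)[cols])
})

test_that("same-day duplicates collapse to a single contact", {
  enc <- mk_enc("p1", rep("2012-01-10", 3), "R74",
                source = c("consultation", "prescription", "prescription"))
  out <- merge_contacts(enc, empty_ehr_tables()$episodes_of_care,
                        empty_ehr_tables()$chronic_diagnoses)
  expect_equal(nrow(out$contacts), 3L)            # conservation before dedupe
  expect_equal(nrow(dedupe_contacts(out$contacts)), 1L)
})

test_that("process-coded events are dropped with an audit count", {
  enc <- mk_enc("p1", c("2012-01-10", "2012-01-11"), c("R74", "K45"))
  out <- merge_contacts(enc, empty_ehr_tables()$episodes_of_care,
                        empty_ehr_tables()$chronic_diagnoses)
  expect_equal(nrow(out$contacts), 1L)
  expect_equal(out$audit$n_process_dropped, 1L)
})
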