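CONTACT_ORIGINS <- c("within_episode_recoded", "extracted_miscoded",
                     "single_encounter", "prescription", "episode_start",
                     "prior_chronic_diagnosis")

#' Flag encounters recorded in the wrong episode of care
#'
#' Symptoms of a disease are legitimately recorded inside that disease's
#' episode of care (e.g. an encounter for coughing inside an asthma
#' episode), so symptom codes are never flagged. An encounter is regarded as
#' incorrectly recorded only when it carries a disease code (component
#' number 70-99), its host episode of care also carries a disease code, and
#' the two codes differ.
#'
#' @param encounter_icpc,episode_icpc Character vectors of ICPC-1 codes
#'   (recycled to common length).
#' @return Logical vector: `TRUE` where the encounter is incorrectly
#'   recorded.
#' @examples
#' flag_incorrect("R05", "R96")  # FALSE: symptom within a disease episode
#' flag_incorrect("K86", "T90")  # TRUE: foreign disease code
#' @export
flag_incorrect <- function(encounter_icpc, episode_icpc) {
  icpc_validate(encounter_icpc)
  icpc_validate(episode_icpc)
  icpc_kind(encounter_icpc) == "disease" &
    icpc_kind(episode_icpc) == "disease" &
    encounter_icpc != episode_icpc
}

#' Merge all contact sources into one diagnosis-coded contact file
#'
#' Implements the cleaning and merging steps that precede episode
#' construction:
#' * correctly recorded encounters and prescriptions inside an episode of
#'   care are recoded to the episode's ICPC code
#'   (origin `within_episode_recoded`);
#' * incorrectly recorded encounters (see [flag_incorrect()]) are extracted
#'   from their host episode and kept as standalone contacts under their own
#'   code (origin `extracted_miscoded`);
#' * single encounters and diagnosis-coded prescriptions outside any episode
#'   of care are kept as-is (origins `single_encounter`, `prescription`);
#' * each episode of care's recorded start date is regarded as an encounter
#'   with the episode's code even if no patient contact is recorded on that
#'   day (origin `episode_start`);
#' * pre-study diagnosis dates of chronic diseases are appended
#'   (origin `prior_chronic_diagnosis`).
#'
#' Uncoded encounters (missing ICPC code) and process-coded events cannot
#' carry a diagnosis and are dropped with an audit count; every other input
#' event yields exactly one contact. Recorded stop dates of episodes of care
#' are never consulted.
#'
#' @param encounters,episodes_of_care,chronic_diagnoses Validated raw tables
#'   (see [read_ehr_tables()]).
#' @param catalog An `icpc_catalog`; used to verify chronic diagnosis codes.
#' @return A list with `contacts` (tibble `patient_id`, `date`, `icpc`,
#'   `origin`, sorted by patient, code, date) and `audit` (named list:
#'   counts by origin, flagged count and fraction of coded encounters and
#'   prescriptions, top flagged codes, drop counts).
#' @export
merge_contacts <- function(encounters, episodes_of_care, chronic_diagnoses,
                           catalog = default_catalog()) {
  enc <- tibble::as_tibble(encounters)
  eoc <- tibble::as_tibble(episodes_of_care)
  cd <- tibble::as_tibble(chronic_diagnoses)

  n_uncoded <- sum(is.na(enc$icpc))
  enc <- enc[!is.na(enc$icpc), ]

  n_process <- 0L
  if (nrow(enc) > 0) {
    proc <- icpc_kind(enc$icpc) == "process"
    n_process <- n_process + sum(proc)
    enc <- enc[!proc, ]
  }

  if (nrow(enc) > 0) {
    ep_code <- eoc$icpc[match(enc$episode_of_care_id, eoc$episode_of_care_id)]
    within <- !is.na(enc$episode_of_care_id)
    if (any(within & is.na(ep_code)))
      stop("Encounter(s) referencing unknown episode_of_care_id", call. = FALSE)
    flagged <- within &
      icpc_kind(enc$icpc) == "disease" &
      icpc_kind(ifelse(within, ep_code, enc$icpc)) == "disease" &
      enc$icpc != ep_code
    flagged[is.na(flagged)] <- FALSE

    contact_code <- ifelse(within & !flagged, ep_code, enc$icpc)
    origin <- dplyr::case_when(
      within & !flagged ~ "within_episode_recoded",
      flagged ~ "extracted_miscoded",
      enc$source == "prescription" ~ "prescription",
      TRUE ~ "single_encounter"
    )
    enc_contacts <- tibble::tibble(patient_id = enc$patient_id,
                                   date = enc$date,
                                   icpc = contact_code, origin = origin)
    # an episode of care coded with a process code would re-introduce one
    proc2 <- icpc_kind(enc_contacts$icpc) == "process"
    n_process <- n_process + sum(proc2)
    enc_contacts <- enc_contacts[!proc2, ]
    flagged_codes <- enc$icpc[flagged]
  } else {
    enc_contacts <- tibble::tibble(patient_id = character(),
                                   date = as.Date(character()),
                                   icpc = character(), origin = character())
    flagged <- logical(0)
    flagged_codes <- character(0)
  }

  if (nrow(eoc) > 0) {
    proc_eoc <- icpc_kind(eoc$icpc) == "process"
    n_process <- n_process + sum(proc_eoc)
    start_contacts <- tibble::tibble(
      patient_id = eoc$patient_id[!proc_eoc],
      date = eoc$recorded_start_date[!proc_eoc],
      icpc = eoc$icpc[!proc_eoc],
      origin = "episode_start")
  } else {
    start_contacts <- enc_contacts[0, ]
  }

  if (nrow(cd) > 0) {
    cat_chr <- lookup_category(catalog, cd$icpc)
    not_chronic <- cat_chr$category != "chronic"
    if (any(not_chronic))
      stop("chronic_diagnoses with non-chronic code(s): ",
           paste(unique(cd$icpc[not_chronic]), collapse = ", "),
           call. = FALSE)
    chron_contacts <- tibble::tibble(patient_id = cd$patient_id,
                                     date = cd$diagnosis_date,
                                     icpc = cd$icpc,
                                     origin = "prior_chronic_diagnosis")
  } else {
    chron_contacts <- enc_contacts[0, ]
  }

  contacts <- dplyr::bind_rows(enc_contacts, start_contacts, chron_contacts)
  contacts <- dplyr::arrange(contacts, .data$patient_id, .data$icpc,
                             .data$date)

  n_coded_events <- nrow(enc)
  top_flagged <- if (length(flagged_codes) > 0) {
    dplyr::arrange(dplyr::count(tibble::tibble(icpc = flagged_codes),
                                .data$icpc), dplyr::desc(.data$n))
  } else {
    tibble::tibble(icpc = character(), n = integer())
  }
  audit <- list(
    counts_by_origin = table(factor(contacts$origin,
                                    levels = CONTACT_ORIGINS)),
    n_flagged = sum(flagged),
    flagged_fraction = if (n_coded_events > 0) sum(flagged) / n_coded_events
                       else 0,
    top_flagged_codes = top_flagged,
    n_uncoded_dropped = n_uncoded,
    n_process_dropped = n_process,
    n_coded_events = n_coded_events
  )
  list(contacts = contacts, audit = audit)
}

#' Collapse same-day duplicate contacts
#'
#' Several events for one (patient, code) on the same day (e.g. an episode
#' start plus a consultation, or repeat prescriptions) carry no extra
#' information for the contact-free-interval logic and are collapsed to one
#' contact before episode construction. The surviving origin is the most
#' informative one in the fixed order of `CONTACT_ORIGINS`.
#'
#' @param contacts Contact tibble from [merge_contacts()].
#' @return Deduplicated contact tibble.
#' @export
dedupe_contacts <- function(contacts) {
  contacts |>
    dplyr::arrange(.data$patient_id, .data$icpc, .data$date,
                   match(.data$origin, CONTACT_ORIGINS)) |>
    dplyr::distinct(.data$patient_id, .data$icpc, .data$date,
                    .keep_all = TRUE)
}
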