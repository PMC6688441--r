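#' Split sorted contact dates into episode runs by contact-free interval
#'
#' Greedy left-to-right partition of a patient's contact dates for one
#' diagnosis code: a new run (future episode of illness) starts whenever the
#' gap from the previous contact is at least the contact-free interval. A
#' gap exactly equal to the interval starts a new episode: an interval of
#' 4 weeks means that a period of 4 weeks between two contacts yields a new
#' episode.
#'
#' @param dates `Date` (or numeric day) vector; sorted and de-duplicated
#'   internally.
#' @param cfi_days Contact-free interval in days (positive integer).
#' @return A list of vectors, each one run of contact dates, in order.
#'   Empty input yields an empty list.
#' @examples
#' split_contacts(c(0, 7, 56, 77), 28)  # the two-episode worked example
#' @export
split_contacts <- function(dates, cfi_days) {
  stopifnot(length(cfi_days) == 1, cfi_days >= 1)
  d <- sort(unique(dates))
  if (length(d) == 0) return(list())
  gaps <- diff(as.numeric(d))
  run <- cumsum(c(TRUE, gaps >= cfi_days))
  unname(split(d, run))
}

#' Connected-components oracle for contact splitting
#'
#' Independent re-derivation of [split_contacts()]: build a graph whose
#' vertices are the distinct contact dates, with an edge between consecutive
#' sorted dates whenever their gap is strictly less than the contact-free
#' interval, and return its connected components. Used in the test suite to
#' verify the greedy partition on randomized inputs.
#'
#' @inheritParams split_contacts
#' @return A list of vectors of dates, one per component, ordered by date.
#' @export
oracle_split <- function(dates, cfi_days) {
  d <- sort(unique(dates))
  n <- length(d)
  if (n == 0) return(list())
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (n > 1) {
    close_pairs <- which(diff(as.numeric(d)) < cfi_days)
    if (length(close_pairs) > 0)
      g <- igraph::add_edges(g, rbind(close_pairs, close_pairs + 1L))
  }
  comp <- igraph::components(g)$membership
  out <- lapply(unique(comp), function(k) d[comp == k])
  out[order(vapply(out, function(x) as.numeric(min(x)), numeric(1)))]
}

#' Construct one episode of illness from a run of contacts
#'
#' For a non-chronic category the episode starts at the first contact and
#' stops half a contact-free interval after the last contact — the recovery
#' date is unknown but lies between the last contact and one full interval
#' later, so half the interval is taken as the expected value. The stop date
#' is capped at the end of the observation interval (`censored = TRUE` when
#' capped).
#'
#' @param run Vector of contact dates (one run from [split_contacts()]).
#' @param category Non-chronic disease category name.
#' @param observation_end Last observed day for this patient (`Date`), or
#'   `NA` for no cap.
#' @return One-row tibble: `start_date`, `stop_date`, `n_contacts`,
#'   `censored`, `provisional_stop` (last contact plus the full interval,
#'   the pre-capping close used mid-algorithm and exposed for debugging).
#' @export
build_episode <- function(run, category, observation_end = as.Date(NA)) {
  stopifnot(length(run) >= 1, category != "chronic")
  half <- half_interval_days(category)
  full <- cfi_days(category)
  first <- min(run)
  last <- max(run)
  stop_date <- last + half
  censored <- FALSE
  if (!is.na(observation_end) && stop_date > observation_end) {
    stop_date <- max(observation_end, last)
    censored <- TRUE
  }
  tibble::tibble(start_date = first, stop_date = stop_date,
                 n_contacts = length(run), censored = censored,
                 provisional_stop = last + full)
}

#' Construct the single chronic episode for one (patient, code)
#'
#' Chronic diseases are considered irreversible: the episode of illness ends
#' only at death or end of observation, and only the start date matters —
#' the earliest of the recorded pre-study diagnosis date and the first
#' contact for the disease.
#'
#' @param contact_dates All contact dates (including any prior diagnosis
#'   date) for the patient and code.
#' @param observation_end End of the patient's last observation interval.
#' @return One-row tibble as in [build_episode()] (with `provisional_stop`
#'   `NA`; chronic episodes have no contact-free interval).
#' @export
build_chronic <- function(contact_dates, observation_end) {
  stopifnot(length(contact_dates) >= 1)
  tibble::tibble(start_date = min(contact_dates),
                 stop_date = observation_end,
                 n_contacts = length(contact_dates),
                 censored = TRUE,
                 provisional_stop = as.Date(NA))
}

#' Construct all episodes of illness from cleaned contacts
#'
#' Groups the merged, cleaned contact file by (patient, ICPC code), looks up
#' each code's disease category, and dispatches to the contact-free-interval
#' logic ([split_contacts()] + [build_episode()]) or to [build_chronic()].
#' Same-day duplicate contacts are collapsed first. Codes absent from the
#' catalog are never silently dropped: they are collected into a skip report
#' attached as the `"skipped"` attribute, with a warning.
#'
#' @param contacts Contact tibble (`patient_id`, `date`, `icpc`, optionally
#'   `origin`), e.g. `merge_contacts(...)$contacts`.
#' @param catalog An `icpc_catalog`.
#' @param windows Observation windows from [observation_windows()].
#' @param trace Keep the per-episode `provisional_stop` column (last contact
#'   plus the full contact-free interval) in the output? Default drops it.
#' @return Tibble with one row per episode of illness: `patient_id`, `icpc`,
#'   `category`, `start_date`, `stop_date`, `n_contacts`, `censored`,
#'   sorted by patient, code, start. Attributes: `"skipped"` (tibble of
#'   uncatalogued codes and contact counts).
#' @export
build_episodes <- function(contacts, catalog = default_catalog(), windows,
                           trace = FALSE) {
  empty <- tibble::tibble(patient_id = character(), icpc = character(),
                          category = character(),
                          start_date = as.Date(character()),
                          stop_date = as.Date(character()),
                          n_contacts = integer(), censored = logical())
  if (trace) empty$provisional_stop <- as.Date(character())
  if (nrow(contacts) == 0) {
    attr(empty, "skipped") <- tibble::tibble(icpc = character(),
                                             n_contacts = integer())
    return(empty)
  }

  cc <- if ("origin" %in% names(contacts)) dedupe_contacts(contacts) else
    dplyr::distinct(dplyr::arrange(contacts, .data$patient_id, .data$icpc,
                                   .data$date),
                    .data$patient_id, .data$icpc, .data$date,
                    .keep_all = TRUE)

  known <- cc$icpc %in% catalog$code
  skipped <- tibble::tibble(icpc = character(), n_contacts = integer())
  if (any(!known)) {
    skipped <- dplyr::count(cc[!known, ], .data$icpc, name = "n_contacts")
    warning("Skipping ", sum(!known), " contact(s) with uncatalogued ",
            "code(s): ", paste(skipped$icpc, collapse = ", "), call. = FALSE)
    cc <- cc[known, ]
  }
  if (nrow(cc) == 0) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  cc$category <- catalog$category[match(cc$icpc, catalog$code)]

  win_by_pat <- split(windows[, c("start", "end")], windows$patient_id)
  groups <- split(cc, paste(cc$patient_id, cc$icpc, sep = "\r"))

  out <- vector("list", length(groups))
  warned_nowin <- FALSE
  warned_outside <- FALSE
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    pid <- g$patient_id[1]
    code <- g$icpc[1]
    cat_name <- g$category[1]
    dates <- sort(g$date)
    w <- win_by_pat[[pid]]

    if (cat_name == "chronic") {
      if (is.null(w) || nrow(w) == 0) {
        if (!warned_nowin) {
          warning("Patient(s) with contacts but no observation window; ",
                  "episodes end at their last contact", call. = FALSE)
          warned_nowin <- TRUE
        }
        obs_end <- max(dates)
      } else {
        obs_end <- max(w$end)
      }
      ep <- build_chronic(dates, obs_end)
    } else {
      runs <- split_contacts(dates, cfi_days(cat_name))
      ep <- dplyr::bind_rows(lapply(runs, function(run) {
        last <- max(run)
        if (is.null(w) || nrow(w) == 0) {
          if (!warned_nowin) {
            warning("Patient(s) with contacts but no observation window; ",
                    "episodes end at their last contact", call. = FALSE)
            warned_nowin <<- TRUE
          }
          obs_end <- as.Date(NA)
        } else {
          inside <- w$start <= last & last <= w$end
          if (any(inside)) {
            obs_end <- w$end[which(inside)[1]]
          } else {
            # run falls in a registration gap: cap against nearest interval
            dist <- pmin(abs(as.numeric(last - w$start)),
                         abs(as.numeric(last - w$end)))
            obs_end <- w$end[which.min(dist)]
            if (!warned_outside) {
              warning("Contact run(s) outside all observation intervals; ",
                      "capped against the nearest interval end",
                      call. = FALSE)
              warned_outside <<- TRUE
            }
          }
        }
        build_episode(run, cat_name, obs_end)
      }))
    }
    ep$patient_id <- pid
    ep$icpc <- code
    ep$category <- cat_name
    out[[i]] <- ep
  }

  res <- dplyr::bind_rows(out)
  res <- res[, c("patient_id", "icpc", "category", "start_date", "stop_date",
                 "n_contacts", "censored", "provisional_stop")]
  if (!trace) res$provisional_stop <- NULL
  res <- dplyr::arrange(res, .data$patient_id, .data$icpc, .data$start_date)
  attr(res, "skipped") <- skipped
  res
}
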