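#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom stats rbinom rexp rgamma rpois runif setNames
#' @importFrom utils packageVersion
NULL

EHR_TABLE_NAMES <- c("patients", "registrations", "encounters",
                     "episodes_of_care", "chronic_diagnoses")

ENCOUNTER_SOURCES <- c("consultation", "prescription", "episode_start")

#' First and last day of a civil calendar quarter
#'
#' Quarters follow the civil calendar: Q1 is January 1 to March 31, and so
#' on. Registration (enrollment claim) records are quarterly, so these
#' boundaries define observed person-time.
#'
#' @param year Integer vector of calendar years.
#' @param quarter Integer vector in 1-4.
#' @return A `Date` vector.
#' @export
quarter_start <- function(year, quarter) {
  stopifnot(all(quarter %in% 1:4))
  as.Date(sprintf("%d-%02d-01", year, 3L * quarter - 2L))
}

#' @rdname quarter_start
#' @export
quarter_end <- function(year, quarter) {
  stopifnot(all(quarter %in% 1:4))
  nxt_y <- ifelse(quarter == 4L, year + 1L, year)
  nxt_q <- ifelse(quarter == 4L, 1L, quarter + 1L)
  quarter_start(nxt_y, nxt_q) - 1L
}

parse_date_col <- function(x, table, col, allow_na = FALSE) {
  x_chr <- as.character(x)
  d <- as.Date(x_chr, format = "%Y-%m-%d", optional = TRUE)
  bad <- (is.na(d) & !is.na(x_chr)) |
    (!is.na(x_chr) & !grepl("^\\d{4}-\\d{2}-\\d{2}$", x_chr))
  if (!allow_na) bad <- bad | is.na(x_chr)
  if (any(bad))
    stop("Unparseable date(s) in ", table, "$", col, ": ",
         paste0("row ", which(bad), " (", ifelse(is.na(x_chr[bad]), "NA",
                                                 x_chr[bad]), ")",
                collapse = ", "),
         call. = FALSE)
  d
}

read_one_table <- function(path) {
  if (!file.exists(path)) stop("Input file not found: ", path, call. = FALSE)
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = c("", "NA"))
}

#' Read the five raw EHR input tables
#'
#' Reads and validates the comma-separated input tables `patients`,
#' `registrations`, `encounters`, `episodes_of_care`, and
#' `chronic_diagnoses` from a directory (files named `<table>.csv`) or from
#' explicitly named paths. All dates must be ISO 8601 (`YYYY-MM-DD`);
#' referential integrity (every encounter's patient and episode-of-care id
#' resolving) is checked, and violations are reported with row numbers.
#'
#' @param dir Directory containing `<table>.csv` files.
#' @param paths Optional named character vector overriding individual table
#'   paths (names among the five table names).
#' @return A named list of validated tibbles, one per table.
#' @seealso [write_ehr_tables()], [validate_ehr()]
#' @export
read_ehr_tables <- function(dir = ".", paths = NULL) {
  files <- setNames(file.path(dir, paste0(EHR_TABLE_NAMES, ".csv")),
                    EHR_TABLE_NAMES)
  if (!is.null(paths)) files[names(paths)] <- paths

  patients <- read_one_table(files[["patients"]])
  registrations <- read_one_table(files[["registrations"]])
  encounters <- read_one_table(files[["encounters"]])
  episodes_of_care <- read_one_table(files[["episodes_of_care"]])
  chronic_diagnoses <- read_one_table(files[["chronic_diagnoses"]])

  patients$death_date <- parse_date_col(patients$death_date, "patients",
                                        "death_date", allow_na = TRUE)
  registrations$year <- as.integer(registrations$year)
  registrations$quarter <- as.integer(registrations$quarter)
  encounters$date <- parse_date_col(encounters$date, "encounters", "date")
  episodes_of_care$recorded_start_date <-
    parse_date_col(episodes_of_care$recorded_start_date, "episodes_of_care",
                   "recorded_start_date")
  episodes_of_care$recorded_stop_date <-
    parse_date_col(episodes_of_care$recorded_stop_date, "episodes_of_care",
                   "recorded_stop_date", allow_na = TRUE)
  chronic_diagnoses$diagnosis_date <-
    parse_date_col(chronic_diagnoses$diagnosis_date, "chronic_diagnoses",
                   "diagnosis_date")

  tables <- list(patients = tibble::as_tibble(patients),
                 registrations = tibble::as_tibble(registrations),
                 encounters = tibble::as_tibble(encounters),
                 episodes_of_care = tibble::as_tibble(episodes_of_care),
                 chronic_diagnoses = tibble::as_tibble(chronic_diagnoses))
  validate_ehr(tables)
  tables
}

#' Validate a set of EHR tables
#'
#' Checks key uniqueness, referential integrity, code well-formedness, and
#' simple date sanity across the five raw tables. Called by
#' [read_ehr_tables()] and usable directly on in-memory tables (e.g. the
#' output of [simulate_ehr()]).
#'
#' @param tables Named list with elements `patients`, `registrations`,
#'   `encounters`, `episodes_of_care`, `chronic_diagnoses`.
#' @return `tables`, invisibly, on success.
#' @export
validate_ehr <- function(tables) {
  stopifnot(all(EHR_TABLE_NAMES %in% names(tables)))
  p <- tables$patients; r <- tables$registrations; e <- tables$encounters
  eoc <- tables$episodes_of_care; cd <- tables$chronic_diagnoses

  if (anyDuplicated(p$patient_id))
    stop("Duplicate patient_id in patients: ",
         paste(unique(p$patient_id[duplicated(p$patient_id)]), collapse = ", "),
         call. = FALSE)
  key <- paste(r$patient_id, r$year, r$quarter)
  if (anyDuplicated(key))
    stop("Duplicate (patient_id, year, quarter) in registrations: rows ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  if (!all(r$quarter %in% 1:4))
    stop("registrations$quarter outside 1-4: rows ",
         paste(which(!r$quarter %in% 1:4), collapse = ", "), call. = FALSE)
  if (nrow(e) > 0 && anyDuplicated(e$encounter_id))
    stop("Duplicate encounter_id in encounters", call. = FALSE)
  if (nrow(eoc) > 0 && anyDuplicated(eoc$episode_of_care_id))
    stop("Duplicate episode_of_care_id in episodes_of_care", call. = FALSE)

  fk <- function(child, col, parent_ids, tab) {
    vals <- child[[col]]
    bad <- !is.na(vals) & !vals %in% parent_ids
    if (any(bad))
      stop("Dangling foreign key in ", tab, "$", col, ": rows ",
           paste(which(bad), collapse = ", "), " (",
           paste(unique(vals[bad]), collapse = ", "), ")", call. = FALSE)
  }
  fk(r, "patient_id", p$patient_id, "registrations")
  fk(e, "patient_id", p$patient_id, "encounters")
  fk(e, "episode_of_care_id", eoc$episode_of_care_id, "encounters")
  fk(eoc, "patient_id", p$patient_id, "episodes_of_care")
  fk(cd, "patient_id", p$patient_id, "chronic_diagnoses")

  icpc_validate(e$icpc, allow_na = TRUE)
  if (nrow(eoc) > 0) icpc_validate(eoc$icpc)
  if (nrow(cd) > 0) icpc_validate(cd$icpc)
  if (nrow(e) > 0 && !all(e$source %in% ENCOUNTER_SOURCES))
    stop("encounters$source must be one of ",
         paste(ENCOUNTER_SOURCES, collapse = ", "), call. = FALSE)

  both <- !is.na(eoc$recorded_stop_date)
  bad_stop <- both & eoc$recorded_stop_date < eoc$recorded_start_date
  if (any(bad_stop))
    stop("episodes_of_care with recorded_stop_date before ",
         "recorded_start_date: rows ", paste(which(bad_stop), collapse = ", "),
         call. = FALSE)
  invisible(tables)
}

#' Write the five EHR tables as CSV
#'
#' @param tables Named list of tables as produced by [read_ehr_tables()] or
#'   [simulate_ehr()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ehr_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in EHR_TABLE_NAMES) {
    readr::write_csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     progress = FALSE, na = "NA")
  }
  invisible(dir)
}

#' Derive observation windows from quarterly registration claims
#'
#' A patient is observed while quarterly enrollment claims are present; a
#' missing claim means the patient was not registered in that quarter (moved
#' away, died, ...). Maximal runs of consecutive registered quarters become
#' closed date intervals. A recorded death date truncates the last interval
#' at day resolution.
#'
#' @param registrations Registrations table (`patient_id`, `year`, `quarter`).
#' @param patients Patients table; `death_date` is used for truncation.
#' @return A tibble with columns `patient_id`, `start`, `end` (class `Date`),
#'   one row per maximal registration interval, sorted by patient and start.
#'   Intervals are closed on both ends and disjoint within a patient.
#' @examples
#' reg <- tibble::tibble(patient_id = "p1", year = 2012L, quarter = 1:4)
#' pat <- tibble::tibble(patient_id = "p1", practice_id = "gp1",
#'                       death_date = as.Date(NA))
#' observation_windows(reg, pat)
#' @export
observation_windows <- function(registrations, patients) {
  if (nrow(registrations) == 0) {
    return(tibble::tibble(patient_id = character(),
                          start = as.Date(character()),
                          end = as.Date(character())))
  }
  death <- setNames(patients$death_date, patients$patient_id)

  r <- registrations[order(registrations$patient_id,
                           registrations$year, registrations$quarter), ]
  qidx <- r$year * 4L + (r$quarter - 1L)
  new_pat <- c(TRUE, r$patient_id[-1] != r$patient_id[-nrow(r)])
  new_run <- new_pat | c(TRUE, diff(qidx) != 1L)
  run_id <- cumsum(new_run)

  first <- !duplicated(run_id)
  last <- !duplicated(run_id, fromLast = TRUE)
  win <- tibble::tibble(
    patient_id = r$patient_id[first],
    start = quarter_start(r$year[first], r$quarter[first]),
    end = quarter_end(r$year[last], r$quarter[last])
  )

  dd <- death[win$patient_id]
  has_death <- !is.na(dd)
  if (any(has_death)) {
    after_death <- has_death & win$start > dd
    if (any(after_death))
      stop("Registration after death for patient(s): ",
           paste(unique(win$patient_id[after_death]), collapse = ", "),
           call. = FALSE)
    win$end[has_death] <- pmin(win$end[has_death], dd[has_death])
  }
  win
}

#' Total observed person-years of a set of windows
#'
#' Untruncated registration quarters contribute exactly 0.25 person-years
#' each; a quarter cut short by death contributes its day count divided by
#' 365.25. This keeps the headline denominator equal to
#' (registered quarters) / 4 while handling deaths at day resolution.
#'
#' @param windows Output of [observation_windows()].
#' @param year Optional calendar year; when given, only person-time falling
#'   inside that year is counted.
#' @return A single non-negative number (person-years).
#' @export
person_years <- function(windows, year = NULL) {
  sum(patient_person_years(windows, year)$py)
}

# per-patient person-years, same quarter-aware convention as person_years()
patient_person_years <- function(windows, year = NULL) {
  if (nrow(windows) == 0)
    return(tibble::tibble(patient_id = character(), py = numeric()))
  if (is.null(year)) {
    years <- unique(c(as.integer(format(windows$start, "%Y")),
                      as.integer(format(windows$end, "%Y"))))
    years <- seq(min(years), max(years))
  } else {
    years <- as.integer(year)
  }
  q <- tidyr::expand_grid(year = years, quarter = 1:4)
  q$qs <- quarter_start(q$year, q$quarter)
  q$qe <- quarter_end(q$year, q$quarter)

  py <- numeric(nrow(windows))
  for (i in seq_len(nrow(q))) {
    ov_start <- pmax(windows$start, q$qs[i])
    ov_end <- pmin(windows$end, q$qe[i])
    days <- as.integer(ov_end - ov_start) + 1L
    days[days < 0L] <- 0L
    full_q <- as.integer(q$qe[i] - q$qs[i]) + 1L
    py <- py + ifelse(days == full_q, 0.25, days / 365.25)
  }
  out <- tibble::tibble(patient_id = windows$patient_id, py = py)
  dplyr::summarise(dplyr::group_by(out, .data$patient_id),
                   py = sum(.data$py), .groups = "drop")
}
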