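#' ICPC-1 chapter letters
#'
#' The seventeen single-letter chapters of the International Classification of
#' Primary Care, version 1 (ICPC-1).
#'
#' @format A character vector of length 17.
#' @export
ICPC_CHAPTERS <- c("A", "B", "D", "F", "H", "K", "L", "N", "P", "R",
                   "S", "T", "U", "W", "X", "Y", "Z")

#' Validate ICPC-1 code strings
#'
#' An ICPC-1 code is one uppercase chapter letter followed by a zero-padded
#' two-digit component number between 01 and 99 (e.g. `"R74"`).
#'
#' @param codes Character vector of candidate codes.
#' @param allow_na Should `NA` entries pass validation? Used for raw encounter
#'   tables where uncoded encounters are legitimate input.
#' @return `codes`, invisibly, if all are well formed; otherwise an error
#'   naming every offending token.
#' @examples
#' icpc_validate(c("R74", "T90"))
#' @export
icpc_validate <- function(codes, allow_na = FALSE) {
  x <- codes
  if (allow_na) x <- x[!is.na(x)]
  ok <- grepl("^[A-Z][0-9]{2}$", x) &
    substr(x, 1, 1) %in% ICPC_CHAPTERS &
    substr(x, 2, 3) != "00"
  ok[is.na(x)] <- FALSE
  if (!all(ok)) {
    bad <- unique(x[!ok])
    stop("Malformed ICPC-1 code(s): ",
         paste(ifelse(is.na(bad), "NA", bad), collapse = ", "),
         call. = FALSE)
  }
  invisible(codes)
}

icpc_number <- function(codes) as.integer(substr(codes, 2, 3))

#' Classify an ICPC-1 code as symptom, process, or disease
#'
#' The component number bands of ICPC-1 determine the kind of a code:
#' 01-29 are symptom codes, 30-69 process codes, and 70-99 disease codes.
#'
#' @param codes Character vector of ICPC-1 codes.
#' @return Character vector with elements `"symptom"`, `"process"`, or
#'   `"disease"`.
#' @examples
#' icpc_kind(c("R05", "R96"))  # symptom, disease
#' @export
icpc_kind <- function(codes) {
  icpc_validate(codes)
  n <- icpc_number(codes)
  dplyr::case_when(
    n <= 29 ~ "symptom",
    n <= 69 ~ "process",
    TRUE    ~ "disease"
  )
}

#' Disease categories and their contact-free intervals
#'
#' Every ICPC-1 symptom or disease code is assigned to one of five disease
#' categories. The four non-chronic categories carry a contact-free interval
#' (CFI): the period within which a patient with a persisting complaint would
#' likely revisit their GP. A gap of at least one CFI between two contacts
#' separates episodes of illness, and half of the CFI is appended after the
#' last contact as the estimated time to recovery. Chronic diseases are
#' considered irreversible and carry no interval.
#'
#' Intervals are expressed in days: 4 weeks = 28, 8 weeks = 56,
#' 16 weeks = 112, 1 year = 365; half-intervals are the floor of half of
#' those (14, 28, 56, 182).
#'
#' @return A tibble with columns `category`, `cfi_days`, `half_interval_days`.
#'   Chronic has `NA` in both interval columns.
#' @export
disease_categories <- function() {
  tibble::tibble(
    category = c("acute_short", "acute_moderate", "acute_long",
                 "long_lasting", "chronic"),
    cfi_days = c(28L, 56L, 112L, 365L, NA_integer_),
    half_interval_days = c(14L, 28L, 56L, 182L, NA_integer_)
  )
}

DISEASE_CATEGORY_NAMES <- c("acute_short", "acute_moderate", "acute_long",
                            "long_lasting", "chronic")

#' Contact-free interval length in days for a disease category
#'
#' @param category Character vector of category names.
#' @return Integer vector of interval lengths; `NA` for `"chronic"`.
#' @export
cfi_days <- function(category) {
  cats <- disease_categories()
  bad <- setdiff(unique(category), cats$category)
  if (length(bad) > 0)
    stop("Unknown disease category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cats$cfi_days[match(category, cats$category)]
}

#' Half contact-free interval length in days for a disease category
#'
#' @inheritParams cfi_days
#' @return Integer vector; `NA` for `"chronic"`.
#' @export
half_interval_days <- function(category) {
  cats <- disease_categories()
  bad <- setdiff(unique(category), cats$category)
  if (length(bad) > 0)
    stop("Unknown disease category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cats$half_interval_days[match(category, cats$category)]
}
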