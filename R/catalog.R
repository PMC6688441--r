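#' Load an ICPC-1 disease-category catalog
#'
#' A catalog maps ICPC-1 symptom and disease codes to their disease category
#' (and hence to their contact-free interval). Catalogs are plain UTF-8 CSV
#' files with the header `code,label,category`, where `category` is one of
#' `acute_short`, `acute_moderate`, `acute_long`, `long_lasting`, `chronic`.
#'
#' Process codes (component numbers 30-69) play no part in episode
#' construction and are rejected at load time, as are duplicate codes and
#' unknown category names. Looking up a code that is not in the catalog is
#' always an explicit error, never a silent default: a partial catalog
#' therefore fails loudly rather than mis-categorising.
#'
#' @param path Path to the catalog CSV file.
#' @return A tibble of class `icpc_catalog` with columns `code`, `label`,
#'   `category`, `cfi_days`, `half_interval_days`, and a `provenance`
#'   attribute recording where the catalog came from.
#' @seealso [default_catalog()], [lookup_category()]
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("Catalog file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("code", "label", "category")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0)
    stop("Catalog is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  new_catalog(raw[needed], provenance = path)
}

new_catalog <- function(df, provenance) {
  df <- tibble::as_tibble(df)
  icpc_validate(df$code)

  dup <- df$code[duplicated(df$code)]
  if (length(dup) > 0)
    stop("Duplicate code(s) in catalog: ", paste(unique(dup), collapse = ", "),
         " (rows ", paste(which(df$code %in% dup), collapse = ", "), ")",
         call. = FALSE)

  bad_cat <- !df$category %in% DISEASE_CATEGORY_NAMES
  if (any(bad_cat))
    stop("Unknown category name(s): ",
         paste(unique(df$category[bad_cat]), collapse = ", "),
         " (rows ", paste(which(bad_cat), collapse = ", "), ")",
         call. = FALSE)

  proc <- icpc_kind(df$code) == "process"
  if (any(proc))
    stop("Process codes (component numbers 30-69) are not admissible in a ",
         "catalog: ", paste(df$code[proc], collapse = ", "),
         " (rows ", paste(which(proc), collapse = ", "), ")",
         call. = FALSE)

  df$cfi_days <- cfi_days(df$category)
  df$half_interval_days <- half_interval_days(df$category)
  attr(df, "provenance") <- provenance
  class(df) <- c("icpc_catalog", class(df))
  df
}

#' The bundled default catalog
#'
#' A deliberately partial catalog covering the most common symptoms and
#' diseases per category, shipped with the package. It is a seed, not the
#' full 685-code assignment: users studying other codes extend it with their
#' own catalog file (same CSV format) via [load_catalog()].
#'
#' @return An `icpc_catalog` tibble.
#' @export
default_catalog <- function() {
  path <- system.file("extdata", "icpc_catalog.csv", package = "ehrepisodes",
                      mustWork = TRUE)
  cat <- load_catalog(path)
  attr(cat, "provenance") <- "ehrepisodes bundled default"
  cat
}

#' Look up the disease category of ICPC-1 codes
#'
#' @param catalog An `icpc_catalog`, e.g. from [load_catalog()].
#' @param codes Character vector of ICPC-1 codes; every code must be present
#'   in the catalog.
#' @return A tibble with one row per element of `codes`, columns `code`,
#'   `category`, `cfi_days`, `half_interval_days`.
#' @examples
#' lookup_category(default_catalog(), "R74")
#' @export
lookup_category <- function(catalog, codes) {
  stopifnot(inherits(catalog, "icpc_catalog"))
  icpc_validate(codes)
  idx <- match(codes, catalog$code)
  if (anyNA(idx))
    stop("Code(s) not in catalog: ",
         paste(unique(codes[is.na(idx)]), collapse = ", "), call. = FALSE)
  tibble::tibble(
    code = codes,
    category = catalog$category[idx],
    cfi_days = catalog$cfi_days[idx],
    half_interval_days = catalog$half_interval_days[idx]
  )
}

#' Write a catalog back to its CSV form
#'
#' @param catalog An `icpc_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "icpc_catalog"))
  readr::write_csv(catalog[, c("code", "label", "category")], path,
                   progress = FALSE)
  invisible(path)
}

#' @export
print.icpc_catalog <- function(x, ...) {
  cat("ICPC-1 disease-category catalog (", nrow(x), " codes; ",
      attr(x, "provenance"), ")\n", sep = "")
  NextMethod()
}
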