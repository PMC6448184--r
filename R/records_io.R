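# Reading and writing the two input CSV dialects and the output directory.

#' Supported provider types
#'
#' The three professional license categories the linkage pipeline ships
#' taxonomy defaults for.
#'
#' @return Character vector of provider type identifiers.
#' @export
supported_provider_types <- function() {
  c("certified_nurse_midwife", "nurse_practitioner", "dentist")
}

#' Default licensure-roster column map
#'
#' State rosters do not share a header convention, so the reader takes a
#' column map from logical field to CSV header. This is the documented
#' default, matching the headers the synthetic generator emits.
#'
#' @return Named list mapping logical fields to header strings.
#' @export
default_licensure_columns <- function() {
  list(
    license_number = "license_number",
    first  = "first_name",
    middle = "middle_name",
    last   = "last_name",
    suffix = "suffix",
    street = "street",
    city   = "city",
    state  = "state",
    zip    = "zip"
  )
}

#' NPPES public-use-file column subset
#'
#' The subset of official NPPES PUF header strings this package consumes.
#'
#' @return Named list mapping logical fields to PUF header strings.
#' @export
nppes_puf_columns <- function() {
  list(
    npi      = "NPI",
    last     = "Provider Last Name (Legal Name)",
    first    = "Provider First Name",
    middle   = "Provider Middle Name",
    suffix   = "Provider Name Suffix Text",
    gender   = "Provider Gender Code",
    phone    = "Provider Business Practice Location Address Telephone Number",
    taxonomy_primary   = "Healthcare Provider Taxonomy Code_1",
    taxonomy_secondary = "Healthcare Provider Taxonomy Code_2",
    m_street = "Provider First Line Business Mailing Address",
    m_city   = "Provider Business Mailing Address City Name",
    m_state  = "Provider Business Mailing Address State Name",
    m_zip    = "Provider Business Mailing Address Postal Code",
    p_street = "Provider First Line Business Practice Location Address",
    p_city   = "Provider Business Practice Location Address City Name",
    p_state  = "Provider Business Practice Location Address State Name",
    p_zip    = "Provider Business Practice Location Address Postal Code",
    other_id      = "Other Provider Identifier_1",
    other_id_type = "Other Provider Identifier Type Code_1"
  )
}

#' @noRd
.read_csv_checked <- function(path) {
  if (!file.exists(path)) .io_error(sprintf("input file not found: %s", path))
  data.table::fread(path, colClasses = "character", header = TRUE,
                    na.strings = NULL, keepLeadingZeros = TRUE)
}

#' @noRd
.clean_state <- function(x) {
  x <- toupper(trimws(x))
  ifelse(grepl("^[A-Z]{2}$", x), x, "")
}

#' Read a state licensure roster
#'
#' Reads one roster CSV (one provider type, one snapshot year). Rows with an
#' empty last name are dropped; duplicate license numbers are collapsed to
#' the first occurrence. Both counts are recorded as attributes — state
#' rosters are known to contain duplicate and stale entries, and nothing is
#' discarded silently.
#'
#' @param path CSV file path. Must exist and carry a header row.
#' @param provider_type One of [supported_provider_types()].
#' @param year Calendar year of the roster snapshot.
#' @param column_map Header map; see [default_licensure_columns()].
#' @return A data.frame of licensure records with attributes `rows_in`,
#'   `n_dropped_empty_last` and `n_duplicates`.
#' @export
read_licensure_list <- function(path, provider_type, year,
                                column_map = default_licensure_columns()) {
  if (!provider_type %in% supported_provider_types()) {
    .config_error(sprintf(
      "unknown provider_type '%s'; supported: %s", provider_type,
      paste(supported_provider_types(), collapse = ", ")))
  }
  dt <- .read_csv_checked(path)
  required <- c("license_number", "first", "last", "street", "city", "state")
  for (f in required) {
    if (!column_map[[f]] %in% names(dt)) {
      .format_error(sprintf("licensure file %s: missing column '%s'",
                            path, column_map[[f]]))
    }
  }
  get_col <- function(f) {
    h <- column_map[[f]]
    if (!is.null(h) && h %in% names(dt)) dt[[h]] else rep("", nrow(dt))
  }
  out <- data.frame(
    license_number = trimws(get_col("license_number")),
    provider_type  = provider_type,
    first  = get_col("first"),
    middle = get_col("middle"),
    last   = get_col("last"),
    suffix = get_col("suffix"),
    street = get_col("street"),
    city   = get_col("city"),
    state  = .clean_state(get_col("state")),
    zip    = trimws(get_col("zip")),
    year   = as.integer(year),
    stringsAsFactors = FALSE
  )
  out$name_raw <- .squish(paste(out$first, out$middle, out$last, out$suffix))
  out$addr_raw <- .squish(paste(out$street, out$city, out$state, out$zip))

  rows_in <- nrow(out)
  keep <- nzchar(trimws(out$last)) & nzchar(out$license_number)
  n_dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  dup <- duplicated(out$license_number)
  n_dup <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rows_in") <- rows_in
  attr(out, "n_dropped_empty_last") <- n_dropped
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Validate a National Provider Identifier
#'
#' An NPI is 10 digits whose final digit is a Luhn check digit computed over
#' the 9-digit base prefixed with the card-issuer constant "80840".
#' Malformed input of any kind returns `FALSE`, never an error.
#'
#' @param s Character vector of candidate identifiers.
#' @return Logical vector.
#' @export
validate_npi <- function(s) {
  s <- as.character(s)
  ok <- !is.na(s) & grepl("^[0-9]{10}$", s)
  res <- logical(length(s))
  if (any(ok)) {
    base <- substr(s[ok], 1L, 9L)
    check <- as.integer(substr(s[ok], 10L, 10L))
    res[ok] <- npi_check_digit(base) == check
  }
  res
}

#' Luhn check digit for a 9-digit NPI base
#'
#' Computes the tenth digit of an NPI from its 9-digit base, using the Luhn
#' algorithm over the base prefixed with "80840". Used both for validation
#' and by the synthetic generator to mint structurally valid identifiers.
#'
#' @param base9 Character vector of 9-digit strings.
#' @return Integer vector of check digits (0-9).
#' @export
npi_check_digit <- function(base9) {
  base9 <- as.character(base9)
  .assert(all(grepl("^[0-9]{9}$", base9)),
          "npi_check_digit: base must be exactly 9 digits")
  payload <- paste0("80840", base9)           # 14 digits
  m <- matrix(as.integer(unlist(strsplit(payload, "", fixed = TRUE))),
              nrow = 14L)
  # Double every second digit from the right; rightmost payload digit is
  # doubled because the check digit will occupy the final (odd) position.
  dbl <- seq(14L, 1L, by = -2L)
  m[dbl, ] <- m[dbl, , drop = FALSE] * 2L
  m[m > 9L] <- m[m > 9L] - 9L
  (10L - colSums(m) %% 10L) %% 10L
}

#' Read an NPPES public-use-file extract
#'
#' Reads one yearly snapshot using the official PUF header strings for the
#' column subset in [nppes_puf_columns()]. Rows whose NPI fails check-digit
#' validation are quarantined to a reject list (attribute `quarantine`,
#' optionally also a CSV), never silently dropped. An empty gender code is
#' mapped to `"unknown"`.
#'
#' @param path CSV file path.
#' @param year Calendar year of the snapshot.
#' @param reject_path Optional path; quarantined raw rows are written there.
#' @return A data.frame of registry records with attributes `rows_in` and
#'   `quarantine`.
#' @export
read_nppes_puf <- function(path, year, reject_path = NULL) {
  cols <- nppes_puf_columns()
  dt <- .read_csv_checked(path)
  required <- c("npi", "last", "first", "taxonomy_primary",
                "p_city", "p_state", "m_city", "m_state")
  for (f in required) {
    if (!cols[[f]] %in% names(dt)) {
      .format_error(sprintf("NPPES file %s: missing column '%s'",
                            path, cols[[f]]))
    }
  }
  get_col <- function(f) {
    h <- cols[[f]]
    if (h %in% names(dt)) dt[[h]] else rep("", nrow(dt))
  }
  gender <- toupper(trimws(get_col("gender")))
  gender[!gender %in% c("M", "F")] <- "unknown"
  other_id <- trimws(get_col("other_id"))
  other_type <- trimws(get_col("other_id_type"))
  other <- ifelse(nzchar(other_id),
                  paste0(ifelse(nzchar(other_type), other_type, "OTH"),
                         ":", other_id),
                  "")
  out <- data.frame(
    npi    = trimws(get_col("npi")),
    first  = get_col("first"),
    middle = get_col("middle"),
    last   = get_col("last"),
    suffix = get_col("suffix"),
    gender = gender,
    phone  = trimws(get_col("phone")),
    taxonomy_primary   = toupper(trimws(get_col("taxonomy_primary"))),
    taxonomy_secondary = toupper(trimws(get_col("taxonomy_secondary"))),
    m_street = get_col("m_street"),
    m_city   = get_col("m_city"),
    m_state  = .clean_state(get_col("m_state")),
    m_zip    = trimws(get_col("m_zip")),
    p_street = get_col("p_street"),
    p_city   = get_col("p_city"),
    p_state  = .clean_state(get_col("p_state")),
    p_zip    = trimws(get_col("p_zip")),
    other_identifiers = other,
    year   = as.integer(year),
    stringsAsFactors = FALSE
  )
  out$name_raw <- .squish(paste(out$first, out$middle, out$last, out$suffix))
  rows_in <- nrow(out)
  valid <- validate_npi(out$npi)
  quarantine <- out[!valid, , drop = FALSE]
  out <- out[valid, , drop = FALSE]
  dup <- duplicated(out$npi)
  if (any(dup)) {
    quarantine <- rbind(quarantine, out[dup, , drop = FALSE])
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  rownames(quarantine) <- NULL
  if (!is.null(reject_path) && nrow(quarantine) > 0L) {
    data.table::fwrite(quarantine, reject_path)
  }
  attr(out, "rows_in") <- rows_in
  attr(out, "quarantine") <- quarantine
  out
}

#' Fixed header of the output directory CSV
#' @return Character vector of column names, in order.
#' @export
directory_columns <- function() {
  c("last_name", "first_name", "npi", "gender", "phone", "taxonomy_code",
    "practice_street", "practice_city", "practice_state", "practice_zip",
    "mailing_street", "mailing_city", "mailing_state", "mailing_zip",
    "license_number", "match_type", "total_score")
}

#' Write the linked provider directory
#'
#' Writes merged records as CSV with the fixed header of
#' [directory_columns()]. Re-reading with [read_directory()] round-trips
#' value-identically.
#'
#' @param records data.frame of linked records (from [merge_records()]).
#' @param path Output CSV path.
#' @return Number of data rows written, invisibly.
#' @export
write_directory <- function(records, path) {
  cols <- directory_columns()
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    empty <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                    cols))
    empty$total_score <- integer(0)
    data.table::fwrite(empty, path)
    return(invisible(0L))
  }
  records <- as.data.frame(records)
  .assert(all(cols %in% names(records)),
          "write_directory: records missing required columns")
  ok <- tryCatch({
    data.table::fwrite(records[, cols], path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) .io_error(sprintf("cannot write directory file: %s", path))
  invisible(nrow(records))
}

#' Read a linked provider directory CSV
#' @param path CSV produced by [write_directory()].
#' @return data.frame with `total_score` integer, all other columns character.
#' @export
read_directory <- function(path) {
  dt <- .read_csv_checked(path)
  .assert(all(directory_columns() %in% names(dt)),
          sprintf("not a directory file (bad header): %s", path),
          "provlink_format_error")
  out <- as.data.frame(dt)[, directory_columns()]
  out$total_score <- as.integer(out$total_score)
  out
}
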