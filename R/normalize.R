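# Canonical keys for names and addresses, the geographic filter, and the
# edit-distance primitive used for misspelling tolerance.

.GENERATIONAL_SUFFIXES <- c("JR", "SR", "II", "III", "IV", "V")

#' Normalize a person name to matching keys
#'
#' Uppercases, strips punctuation (apostrophes removed, hyphens treated as
#' token separators) and generational suffixes (JR, SR, II, III, IV), and
#' tokenizes compound surnames so that e.g. a two- and a three-token form of
#' the same family name can be compared token-wise.
#'
#' @param first,last Character vectors (recycled to a common length).
#' @param suffix Optional suffix field; also stripped if embedded in `last`.
#' @return data.frame with columns `first_key`, `last_key` and
#'   `last_tokens` (space-separated token string).
#' @export
normalize_person_name <- function(first, last, suffix = "") {
  n <- max(length(first), length(last))
  first <- rep_len(as.character(first), n)
  last  <- rep_len(as.character(last), n)
  first_key <- .clean_key(first)
  # keep only the leading token of a multi-word first name field
  first_key <- sub(" .*$", "", first_key)
  last_key <- .clean_key(last)
  toks <- strsplit(last_key, " ", fixed = TRUE)
  toks <- lapply(toks, function(t) t[!t %in% .GENERATIONAL_SUFFIXES])
  last_key <- vapply(toks, paste, "", collapse = " ")
  data.frame(first_key = first_key,
             last_key = last_key,
             last_tokens = last_key,   # tokens are space-delimited in the key
             stringsAsFactors = FALSE)
}

#' @noRd
.suffix_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- system.file("extdata", "street_suffixes.tsv",
                       package = "provlink", mustWork = TRUE)
      tab <- utils::read.delim(p, colClasses = "character")
      cache <<- setNames(tab$abbr, tab$full)
    }
    cache
  }
})

.UNIT_DESIGNATORS <- c("APT", "APARTMENT", "STE", "SUITE", "UNIT", "RM",
                       "ROOM", "FLOOR", "FL", "BLDG", "BUILDING", "NO")

#' Normalize a postal address to matching keys
#'
#' Uppercases, strips punctuation, canonicalizes USPS street suffixes
#' (AVENUE to AVE, ROAD to RD, ...) and drops unit/suite designators with
#' their following token. The city key is the cleaned town name only.
#'
#' @param street,city Character vectors (recycled).
#' @return data.frame with columns `street_key`, `city_key`.
#' @export
normalize_address <- function(street, city) {
  n <- max(length(street), length(city))
  street <- rep_len(as.character(street), n)
  city   <- rep_len(as.character(city), n)
  map <- .suffix_map()
  street_key <- vapply(strsplit(.clean_key(street), " ", fixed = TRUE),
                       function(t) {
    if (length(t) == 0L) return("")
    drop <- logical(length(t))
    u <- which(t %in% .UNIT_DESIGNATORS)
    if (length(u)) {
      drop[u] <- TRUE
      drop[pmin(u + 1L, length(t))] <- TRUE
    }
    t <- t[!drop]
    hit <- t %in% names(map)
    t[hit] <- map[t[hit]]
    paste(t, collapse = " ")
  }, "")
  data.frame(street_key = street_key,
             city_key = .clean_key(city),
             stringsAsFactors = FALSE)
}

#' Geographic filter for registry records
#'
#' Keeps a record iff the state of either its practice or its mailing
#' address is in the allowed set. The default set is the study region:
#' Connecticut, its neighbours (MA, NY, RI) and Florida, where a sizeable
#' share of residents live part of the year.
#'
#' @param records NPPES-style data.frame.
#' @param states Set of two-letter state codes; must be non-empty.
#' @return Filtered data.frame with attribute `n_dropped`.
#' @export
filter_by_location <- function(records, states = region_states()) {
  if (length(states) == 0L) .config_error("location filter: empty state set")
  states <- toupper(states)
  keep <- records$p_state %in% states | records$m_state %in% states
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Default location-filter state set
#' @return Character vector `c("CT","MA","NY","RI","FL")`.
#' @export
region_states <- function() c("CT", "MA", "NY", "RI", "FL")

#' Levenshtein distance between normalized keys
#'
#' Unit-cost insert/delete/substitute edit distance, vectorized
#' elementwise. This is the primitive behind the fuzzy equality rule that
#' tolerates transcription misspellings.
#'
#' @param a,b Character vectors (recycled to a common length).
#' @return Non-negative integer vector.
#' @export
name_edit_distance <- function(a, b) .pair_dist(a, b)

# Fuzzy equality tier for a key pair: tolerance 2 when the longer key has
# at least 5 characters, else 1. Keyed on the longer side so a deletion
# typo of a long name does not downgrade its own tier; a doubled-letter
# misspelling of a 5-letter name passes while a genuine surname
# replacement (distance 5) never does.
#' @noRd
.fuzzy_tol <- function(a, b) {
  ifelse(pmax(nchar(a), nchar(b)) >= 5L, 2L, 1L)
}

# Keys shorter than 3 characters never match fuzzily (a lone initial must
# not absorb a different initial).
#' @noRd
.fuzzy_eq <- function(a, b) {
  eq <- a == b & nzchar(a)
  idx <- which(!eq & nchar(a) >= 3L & nchar(b) >= 3L)
  if (length(idx)) {
    tol <- .fuzzy_tol(a[idx], b[idx])
    plausible <- abs(nchar(a[idx]) - nchar(b[idx])) <= tol
    if (any(plausible)) {
      j <- idx[plausible]
      eq[j] <- .pair_dist(a[j], b[j]) <= .fuzzy_tol(a[j], b[j])
    }
  }
  eq
}
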