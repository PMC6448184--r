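# Entity-recognition matching: classify candidate (licensure, registry)
# pairs into the seven name/address match types, with blocking for scale.

#' The seven name/address match types
#'
#' A match type names which entities agree between a roster record and a
#' registry record. The grid {first+last, last-only} x {city+street, city,
#' street, neither} has eight cells; a bare surname agreement with no
#' corroborating address carries no discriminating power and is the one
#' excluded cell, leaving seven types. Rank 1 is strongest; full-name
#' families dominate, and within a family city outranks street because town
#' names suffer fewer transcription errors.
#'
#' @return data.frame with columns `code`, `rank`, `first_required`,
#'   `city_required`, `street_required`, ordered by rank.
#' @export
enumerate_match_types <- function() {
  data.frame(
    code = c("FL_CS", "FL_C", "FL_S", "FL", "L_CS", "L_C", "L_S"),
    rank = 1:7,
    first_required  = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    city_required   = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    street_required = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

# ---- key preparation --------------------------------------------------

#' @noRd
.add_lic_keys <- function(df) {
  nm <- normalize_person_name(df$first, df$last)
  ad <- normalize_address(df$street, df$city)
  df$first_key <- nm$first_key
  df$last_key <- nm$last_key
  df$city_key <- ad$city_key
  df$street_key <- ad$street_key
  df
}

#' @noRd
.add_np_keys <- function(df) {
  nm <- normalize_person_name(df$first, df$last)
  pa <- normalize_address(df$p_street, df$p_city)
  ma <- normalize_address(df$m_street, df$m_city)
  df$first_key <- nm$first_key
  df$last_key <- nm$last_key
  df$p_city_key <- pa$city_key
  df$p_street_key <- pa$street_key
  df$m_city_key <- ma$city_key
  df$m_street_key <- ma$street_key
  df
}

# ---- agreement rules --------------------------------------------------

# Surnames agree when the keys are exactly equal, when one token set is a
# subset of the other (compound-surname rule: "BROWN SMITH" vs
# "BROWN JACKSON SMITH"), or — with fuzzy comparison on — within the tiered
# edit-distance tolerance on the space-free key.
#' @noRd
.last_agree <- function(a, b, fuzzy) {
  ok <- a == b & nzchar(a)
  rest <- which(!ok & nzchar(a) & nzchar(b))
  if (length(rest)) {
    ta <- strsplit(a[rest], " ", fixed = TRUE)
    tb <- strsplit(b[rest], " ", fixed = TRUE)
    subset_ok <- mapply(function(x, y) {
      all(x %in% y) || all(y %in% x)
    }, ta, tb, USE.NAMES = FALSE)
    ok[rest] <- subset_ok
    if (fuzzy) {
      rest2 <- rest[!subset_ok]
      if (length(rest2)) {
        ok[rest2] <- .fuzzy_eq(gsub(" ", "", a[rest2], fixed = TRUE),
                               gsub(" ", "", b[rest2], fixed = TRUE))
      }
    }
  }
  ok
}

# First names agree on exact equality, on the initial-vs-full rule
# (H vs HELEN), or fuzzily. The initial rule reflects rosters that
# abbreviate; it does not bridge a middle name used as a first name.
#' @noRd
.first_agree <- function(a, b, fuzzy) {
  ok <- a == b & nzchar(a)
  ini <- (nchar(a) == 1L & nzchar(b) & a == substr(b, 1L, 1L)) |
         (nchar(b) == 1L & nzchar(a) & b == substr(a, 1L, 1L))
  ok <- ok | ini
  if (fuzzy) {
    idx <- which(!ok & nzchar(a) & nzchar(b))
    if (length(idx)) ok[idx] <- .fuzzy_eq(a[idx], b[idx])
  }
  ok
}

#' @noRd
.entity_agree <- function(a, b, fuzzy) {
  if (fuzzy) .fuzzy_eq(a, b) else (a == b & nzchar(a))
}

# Vectorized classification over aligned key columns. Returns per-pair
# agreement flags and the match-type code/rank.
#' @noRd
.classify_pairs <- function(lic, np, fuzzy) {
  last_ok <- .last_agree(lic$last_key, np$last_key, fuzzy)
  first_ok <- .first_agree(lic$first_key, np$first_key, fuzzy)
  # licensure address compared against both registry addresses (OR)
  city_ok <- .entity_agree(lic$city_key, np$p_city_key, fuzzy) |
             .entity_agree(lic$city_key, np$m_city_key, fuzzy)
  street_ok <- .entity_agree(lic$street_key, np$p_street_key, fuzzy) |
               .entity_agree(lic$street_key, np$m_street_key, fuzzy)
  type <- rep("NONE", length(last_ok))
  fl <- last_ok & first_ok
  type[fl & city_ok & street_ok] <- "FL_CS"
  type[fl & city_ok & !street_ok] <- "FL_C"
  type[fl & !city_ok & street_ok] <- "FL_S"
  type[fl & !city_ok & !street_ok] <- "FL"
  lo <- last_ok & !first_ok
  type[lo & city_ok & street_ok] <- "L_CS"
  type[lo & city_ok & !street_ok] <- "L_C"
  type[lo & !city_ok & street_ok] <- "L_S"
  mt <- enumerate_match_types()
  list(last_ok = last_ok, first_ok = first_ok & last_ok,
       city_ok = city_ok & last_ok, street_ok = street_ok & last_ok,
       type = type, rank = mt$rank[match(type, mt$code)])
}

#' Classify one candidate pair into a match type
#'
#' Returns the strongest match type whose required entities all agree under
#' the configured equality rule (exact or edit-distance tolerant), or
#' `"NONE"` when the last names disagree or only a bare surname agrees.
#'
#' @param lic One-row licensure data.frame (as from [read_licensure_list()]).
#' @param rec One-row registry data.frame (as from [read_nppes_puf()]).
#' @param config A [linkage_config()].
#' @return Match type code, one of `enumerate_match_types()$code` or `"NONE"`.
#' @export
classify_match <- function(lic, rec, config = linkage_config()) {
  lic <- .add_lic_keys(as.data.frame(lic))
  rec <- .add_np_keys(as.data.frame(rec))
  .classify_pairs(lic, rec, config$fuzzy)$type
}

# ---- blocking ---------------------------------------------------------

# All strings reachable from s by deleting up to k characters (including s
# itself). Two strings within Levenshtein distance k always share a member
# of their depth-k deletion neighbourhoods (the FastSS property), which is
# what makes this blocking key complete under the fuzzy tolerance.
#' @noRd
.del_variants <- function(s, k) {
  out <- s
  frontier <- s
  for (d in seq_len(k)) {
    nxt <- unlist(lapply(frontier, function(x) {
      n <- nchar(x)
      if (n <= 1L) return(character(0))
      vapply(seq_len(n), function(i) {
        paste0(substr(x, 1L, i - 1L), substr(x, i + 1L, n))
      }, "")
    }))
    nxt <- unique(nxt)
    out <- unique(c(out, nxt))
    frontier <- nxt
  }
  out
}

#' @noRd
.blocking_keys <- function(last_key, fuzzy) {
  nospace <- gsub(" ", "", last_key, fixed = TRUE)
  toks <- strsplit(last_key, " ", fixed = TRUE)
  uk <- unique(nospace)
  # depth must cover the largest tolerance the key can participate in
  # (tier is keyed on the longer side of a pair, so 2 whenever fuzzy)
  depth <- if (fuzzy) ifelse(nchar(uk) >= 3L, 2L, 1L)
           else rep(0L, length(uk))
  vars <- lapply(seq_along(uk), function(i) {
    paste0("D:", .del_variants(uk[i], depth[i]))
  })
  lapply(seq_along(last_key), function(i) {
    c(vars[[match(nospace[i], uk)]], paste0("T:", toks[[i]]))
  })
}

#' Candidate pair generation by blocking
#'
#' Emits every (licensure, registry) index pair that shares a blocking key.
#' Keys are the surname tokens (for the compound-surname subset rule) plus
#' the deletion neighbourhood of the space-free surname key, whose depth
#' mirrors the fuzzy tolerance tiers — so no pair that [classify_match()]
#' would accept is ever excluded.
#'
#' @param lic_df Licensure data.frame.
#' @param nppes_df Registry data.frame.
#' @param config A [linkage_config()].
#' @return data.frame with integer columns `li`, `ni` (row indices).
#' @export
block_candidates <- function(lic_df, nppes_df, config = linkage_config()) {
  if (nrow(lic_df) == 0L || nrow(nppes_df) == 0L) {
    return(data.frame(li = integer(0), ni = integer(0)))
  }
  if (!"last_key" %in% names(lic_df)) lic_df <- .add_lic_keys(lic_df)
  if (!"last_key" %in% names(nppes_df)) nppes_df <- .add_np_keys(nppes_df)
  kl <- .blocking_keys(lic_df$last_key, config$fuzzy)
  kn <- .blocking_keys(nppes_df$last_key, config$fuzzy)
  dtl <- data.table::data.table(
    bkey = unlist(kl),
    li = rep.int(seq_along(kl), lengths(kl)))
  dtn <- data.table::data.table(
    bkey = unlist(kn),
    ni = rep.int(seq_along(kn), lengths(kn)))
  pairs <- merge(dtl, dtn, by = "bkey", allow.cartesian = TRUE)
  pairs <- unique(pairs[, c("li", "ni")])
  data.table::setorder(pairs, li, ni)
  as.data.frame(pairs)
}

# ---- multi-year matching ----------------------------------------------

#' Match a roster against all registry snapshots in the window
#'
#' For each licensure record, finds registry candidates in every yearly
#' snapshot and aggregates, per (license number, NPI) pair, the set of
#' years in which each entity (last name, first name, city, street)
#' agreed. A year contributes only when the pair matched at all that year
#' (i.e. last names agreed with some corroboration). The candidate carries
#' its strongest match type over the window.
#'
#' @param lic_df Licensure data.frame.
#' @param nppes_snapshots Named list: `"<year>"` -> registry data.frame.
#'   Must cover every year of the scoring window.
#' @param config A [linkage_config()].
#' @return data.frame of candidates: `license_number`, `npi`, `match_type`,
#'   `rank`, `recent_year`, and comma-joined year sets `years_last`,
#'   `years_first`, `years_city`, `years_street`.
#' @export
match_all <- function(lic_df, nppes_snapshots, config = linkage_config()) {
  years <- window_years(config$window)
  missing_years <- setdiff(as.character(years), names(nppes_snapshots))
  if (length(missing_years)) {
    .config_error(sprintf("no registry snapshot for window year(s): %s",
                          paste(missing_years, collapse = ", ")))
  }
  lic_df <- as.data.frame(lic_df)
  if (nrow(lic_df) == 0L) return(.empty_candidates())
  lic_k <- .add_lic_keys(lic_df)
  acc <- vector("list", length(years))
  for (j in seq_along(years)) {
    y <- years[j]
    np <- as.data.frame(nppes_snapshots[[as.character(y)]])
    if (nrow(np) == 0L) next
    np_k <- .add_np_keys(np)
    pairs <- if (config$block) {
      block_candidates(lic_k, np_k, config)
    } else {
      as.data.frame(data.table::CJ(li = seq_len(nrow(lic_k)),
                                   ni = seq_len(nrow(np_k))))
    }
    if (nrow(pairs) == 0L) next
    cl <- .classify_pairs(lic_k[pairs$li, , drop = FALSE],
                          np_k[pairs$ni, , drop = FALSE],
                          config$fuzzy)
    keep <- cl$type != "NONE"
    if (!any(keep)) next
    acc[[j]] <- data.table::data.table(
      license_number = lic_k$license_number[pairs$li[keep]],
      npi = np_k$npi[pairs$ni[keep]],
      year = y,
      first_ok = cl$first_ok[keep],
      city_ok = cl$city_ok[keep],
      street_ok = cl$street_ok[keep],
      rank = cl$rank[keep]
    )
  }
  acc <- acc[!vapply(acc, is.null, TRUE)]
  if (length(acc) == 0L) return(.empty_candidates())
  all_years <- data.table::rbindlist(acc)
  mt <- enumerate_match_types()
  year <- first_ok <- city_ok <- street_ok <- NULL  # R CMD check
  out <- all_years[, list(
    rank = min(rank),
    recent_year = max(year),
    years_last = paste(sort(year), collapse = ","),
    years_first = paste(sort(year[first_ok]), collapse = ","),
    years_city = paste(sort(year[city_ok]), collapse = ","),
    years_street = paste(sort(year[street_ok]), collapse = ",")
  ), by = c("license_number", "npi")]
  out$match_type <- mt$code[match(out$rank, mt$rank)]
  data.table::setorder(out, license_number, npi)
  out <- as.data.frame(out)
  out[, c("license_number", "npi", "match_type", "rank", "recent_year",
          "years_last", "years_first", "years_city", "years_street")]
}

#' @noRd
.empty_candidates <- function() {
  data.frame(license_number = character(0), npi = character(0),
             match_type = character(0), rank = integer(0),
             recent_year = integer(0), years_last = character(0),
             years_first = character(0), years_city = character(0),
             years_street = character(0), stringsAsFactors = FALSE)
}
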