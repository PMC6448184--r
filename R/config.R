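# Run configuration shared by the matching engine, scorer and pipeline.

#' Scoring window
#'
#' The span of yearly registry snapshots over which temporal points are
#' assigned. The default is the five consecutive study years 2013-2017.
#'
#' @param start_year,end_year Integer calendar years, `end_year >= start_year`.
#' @return Object of class `scoring_window`.
#' @export
scoring_window <- function(start_year = 2013L, end_year = 2017L) {
  start_year <- as.integer(start_year)
  end_year <- as.integer(end_year)
  if (is.na(start_year) || is.na(end_year) || end_year < start_year) {
    .config_error("scoring window: need end_year >= start_year")
  }
  structure(list(start_year = start_year, end_year = end_year),
            class = "scoring_window")
}

#' @export
print.scoring_window <- function(x, ...) {
  cat(sprintf("<scoring_window> %d-%d (%d years)\n",
              x$start_year, x$end_year, x$end_year - x$start_year + 1L))
  invisible(x)
}

#' Years covered by a scoring window
#' @param window A [scoring_window()].
#' @return Integer vector of calendar years.
#' @export
window_years <- function(window) seq(window$start_year, window$end_year)

#' Linkage run configuration
#'
#' Collects every tunable of the pipeline. The acceptance threshold of 12
#' points is this package's default, not an externally fixed constant: it
#' admits a full-name match in recent years with at least one corroborating
#' address entity, and rejects any single-entity coincidence (maximum 5
#' points) as well as stale name-only matches.
#'
#' @param provider_type One of [supported_provider_types()].
#' @param window A [scoring_window()].
#' @param threshold Integer in \[0, 20\]; minimum total score to accept.
#' @param fuzzy Logical; edit-distance-tolerant entity comparison.
#' @param block Logical; use blocking instead of all-pairs comparison.
#' @param states Location-filter state set.
#' @param taxonomy_table Taxonomy table (see [load_taxonomy_table()]).
#' @param licensure_columns Roster header map.
#' @return Object of class `linkage_config`.
#' @export
linkage_config <- function(provider_type = "certified_nurse_midwife",
                           window = scoring_window(),
                           threshold = 12L,
                           fuzzy = TRUE,
                           block = TRUE,
                           states = region_states(),
                           taxonomy_table = load_taxonomy_table(),
                           licensure_columns = default_licensure_columns()) {
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 0L || threshold > 20L) {
    .config_error("threshold must be an integer in [0, 20]")
  }
  if (!inherits(window, "scoring_window")) {
    .config_error("window must be a scoring_window object")
  }
  structure(list(
    provider_type = provider_type,
    window = window,
    threshold = threshold,
    fuzzy = isTRUE(fuzzy),
    block = isTRUE(block),
    states = states,
    taxonomy_table = taxonomy_table,
    licensure_columns = licensure_columns
  ), class = "linkage_config")
}

#' @export
print.linkage_config <- function(x, ...) {
  cat("<linkage_config>\n",
      sprintf("  provider_type: %s\n", x$provider_type),
      sprintf("  window: %d-%d, threshold: %d\n",
              x$window$start_year, x$window$end_year, x$threshold),
      sprintf("  fuzzy: %s, block: %s, states: %s\n",
              x$fuzzy, x$block, paste(x$states, collapse = ",")),
      sep = "")
  invisible(x)
}

# Serializable view of a config (for the effective-config file written
# beside every run's outputs).
#' @noRd
.config_as_list <- function(config) {
  list(
    provider_type = config$provider_type,
    window = list(start = config$window$start_year,
                  end = config$window$end_year),
    threshold = config$threshold,
    fuzzy = config$fuzzy,
    block = config$block,
    states = config$states
  )
}
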