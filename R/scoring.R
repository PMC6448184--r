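# Temporal point scoring: per-entity points over the snapshot window,
# summed across the four entities and thresholded.

#' Temporal score for one entity
#'
#' An entity (last name, first name, city or street) that matched in the
#' window's most recent year earns 5 points; for each year the most recent
#' match recedes from the end of the window, 1 point is taken off. The
#' score floors at 0 (relevant only for windows longer than six years) and
#' an entity that never matched scores 0.
#'
#' @param match_years Integer vector (possibly empty) of years in which the
#'   entity matched. Must lie within the window.
#' @param window A [scoring_window()].
#' @return Integer score in \[0, 5\].
#' @export
score_entity <- function(match_years, window = scoring_window()) {
  match_years <- as.integer(match_years)
  match_years <- match_years[!is.na(match_years)]
  if (length(match_years) == 0L) return(0L)
  if (any(match_years < window$start_year | match_years > window$end_year)) {
    .input_error("score_entity: match year outside the scoring window")
  }
  max(0L, 5L - (window$end_year - max(match_years)))
}

#' @noRd
.parse_years <- function(s) {
  if (is.na(s) || !nzchar(s)) integer(0)
  else as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
}

#' Score one match candidate
#'
#' Applies [score_entity()] independently to the four entities of a
#' candidate and sums them into a total in \[0, 20\].
#'
#' @param candidate One-row candidate data.frame (from [match_all()]).
#' @param window A [scoring_window()].
#' @return Named integer vector with components `last`, `first`, `city`,
#'   `street`, `total`.
#' @export
score_candidate <- function(candidate, window = scoring_window()) {
  v <- c(
    last   = score_entity(.parse_years(candidate$years_last[1L]), window),
    first  = score_entity(.parse_years(candidate$years_first[1L]), window),
    city   = score_entity(.parse_years(candidate$years_city[1L]), window),
    street = score_entity(.parse_years(candidate$years_street[1L]), window)
  )
  c(v, total = sum(v))
}

#' Score all candidates
#'
#' Vectorized [score_candidate()] over a candidate table.
#'
#' @param candidates Candidate data.frame from [match_all()].
#' @param window A [scoring_window()].
#' @return The input with integer columns `score_last`, `score_first`,
#'   `score_city`, `score_street`, `total` appended.
#' @export
score_candidates <- function(candidates, window = scoring_window()) {
  score_col <- function(col) {
    vapply(candidates[[col]], function(s) {
      score_entity(.parse_years(s), window)
    }, integer(1), USE.NAMES = FALSE)
  }
  candidates$score_last <- score_col("years_last")
  candidates$score_first <- score_col("years_first")
  candidates$score_city <- score_col("years_city")
  candidates$score_street <- score_col("years_street")
  candidates$total <- candidates$score_last + candidates$score_first +
    candidates$score_city + candidates$score_street
  candidates
}

#' Threshold scored candidates
#'
#' Keeps candidates whose total score meets the acceptance threshold,
#' preserving input order.
#'
#' @param candidates Scored candidate data.frame (see [score_candidates()]).
#' @param threshold Integer in \[0, 20\].
#' @return The accepted subset.
#' @export
apply_threshold <- function(candidates, threshold) {
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 0L || threshold > 20L) {
    .config_error("threshold must be in [0, 20]")
  }
  out <- candidates[candidates$total >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
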