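# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
.assert <- function(cond, msg, class = "provlink_error") {
  if (!isTRUE(cond)) {
    stop(structure(
      class = c(class, "error", "condition"),
      list(message = msg, call = sys.call(-1))
    ))
  }
  invisible(TRUE)
}

.config_error <- function(msg) .assert(FALSE, msg, "provlink_config_error")
.format_error <- function(msg) .assert(FALSE, msg, "provlink_format_error")
.io_error     <- function(msg) .assert(FALSE, msg, "provlink_io_error")
.input_error  <- function(msg) .assert(FALSE, msg, "provlink_input_error")

#' @noRd
.squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Uppercase, drop punctuation (apostrophes/periods removed, hyphens and
# slashes become token separators), collapse whitespace.
#' @noRd
.clean_key <- function(x) {
  x <- toupper(ifelse(is.na(x), "", x))
  x <- gsub("[-/]", " ", x)
  x <- gsub("[^A-Z0-9 ]", "", x)
  .squish(x)
}

# Elementwise Levenshtein distance, deduplicated so repeated pairs cost one
# adist() call. Used by the matching engine on already-normalized keys.
#' @noRd
.pair_dist <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  key <- paste0(a, "\r", b)
  u <- !duplicated(key)
  ud <- mapply(function(x, y) utils::adist(x, y)[1L, 1L], a[u], b[u],
               USE.NAMES = FALSE)
  as.integer(ud[match(key, key[u])])
}

# Derive a 32-bit substream seed from a master seed and an index, so the
# first k identities of a cohort are invariant to the total size n.
#' @noRd
.substream_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + as.numeric(i) * 16807) %%
               2147483587)
}
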