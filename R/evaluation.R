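# Recall/precision assessment against ground truth, plus an error-channel
# classifier for false negatives.

#' Recall
#' @param tp,fn True-positive and false-negative counts; `tp + fn` must be
#'   positive.
#' @return `tp / (tp + fn)`.
#' @export
recall <- function(tp, fn) {
  if (tp + fn <= 0) .input_error("recall undefined: tp + fn == 0")
  tp / (tp + fn)
}

#' Precision
#' @param tp,fp True-positive and false-positive counts; `tp + fp` must be
#'   positive.
#' @return `tp / (tp + fp)`.
#' @export
precision <- function(tp, fp) {
  if (tp + fp <= 0) .input_error("precision undefined: tp + fp == 0")
  tp / (tp + fp)
}

#' Compare predicted links to ground truth
#'
#' A predicted link is a true positive iff its (license number, NPI) pair
#' appears in the truth table — the unit of correctness is the identity
#' pairing, not field-value agreement. Any other predicted link is a false
#' positive; a truth link (with a non-empty NPI) that was not predicted is
#' a false negative. Truth rows with no NPI (no national record exists)
#' contribute to neither TP nor FN, but predicting any link for them is a
#' false positive. False negatives are attributed to their truth error
#' label.
#'
#' @param predicted data.frame with `license_number` and `npi` (e.g. a
#'   directory from [build_directory()] or [read_directory()]).
#' @param truth Truth data.frame (see [read_truth()]).
#' @return Object of class `provlink_eval`: `tp`, `fp`, `fn`, `recall`,
#'   `precision`, `error_breakdown`, plus the `fp_pairs` and `fn_pairs`
#'   tables.
#' @export
compare_to_truth <- function(predicted, truth) {
  .assert(all(c("license_number", "npi") %in% names(predicted)),
          "predicted table needs license_number and npi columns",
          "provlink_input_error")
  .assert(all(c("license_number", "npi", "error_labels") %in% names(truth)),
          "truth table needs license_number, npi, error_labels",
          "provlink_input_error")
  unknown <- setdiff(unique(predicted$license_number),
                     truth$license_number)
  if (length(unknown)) {
    .input_error(sprintf(
      "prediction/truth cohort mismatch: %d predicted license(s) absent from truth",
      length(unknown)))
  }
  truth_key <- paste(truth$license_number, truth$npi, sep = "\r")
  pred_key <- paste(predicted$license_number, predicted$npi, sep = "\r")
  linkable <- nzchar(truth$npi) & !is.na(truth$npi)

  is_tp <- pred_key %in% truth_key[linkable]
  tp <- sum(is_tp)
  fp_pairs <- predicted[!is_tp, c("license_number", "npi"), drop = FALSE]
  fn_mask <- linkable & !(truth_key %in% pred_key)
  fn_pairs <- truth[fn_mask, , drop = FALSE]
  rownames(fp_pairs) <- rownames(fn_pairs) <- NULL

  breakdown <- classify_false_results(fn_pairs)
  structure(list(
    tp = tp, fp = nrow(fp_pairs), fn = nrow(fn_pairs),
    recall = if (tp + nrow(fn_pairs) > 0) recall(tp, nrow(fn_pairs))
             else NA_real_,
    precision = if (tp + nrow(fp_pairs) > 0) precision(tp, nrow(fp_pairs))
                else NA_real_,
    error_breakdown = breakdown,
    fp_pairs = fp_pairs, fn_pairs = fn_pairs
  ), class = "provlink_eval")
}

#' Attribute false negatives to their error channels
#'
#' @param fn_pairs Truth rows that were missed (must carry `error_labels`).
#' @return Named integer vector: error label -> FN count. Labels of
#'   `"none"` are reported as `"other"`.
#' @export
classify_false_results <- function(fn_pairs) {
  if (is.null(fn_pairs) || nrow(fn_pairs) == 0L) {
    return(integer(0))
  }
  labels <- fn_pairs$error_labels
  labels[!nzchar(labels) | labels == "none"] <- "other"
  tab <- table(labels)
  setNames(as.integer(tab), names(tab))
}

#' @export
print.provlink_eval <- function(x, ...) {
  cat("<provlink_eval>\n")
  cat(sprintf("  tp=%d fp=%d fn=%d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  recall=%.4f precision=%.4f\n", x$recall, x$precision))
  if (length(x$error_breakdown)) {
    cat("  false negatives by channel:\n")
    for (nm in names(x$error_breakdown)) {
      cat(sprintf("    %-16s %d\n", nm, x$error_breakdown[[nm]]))
    }
  }
  invisible(x)
}

#' @noRd
.eval_as_list <- function(x) {
  list(tp = x$tp, fp = x$fp, fn = x$fn, recall = x$recall,
       precision = x$precision,
       error_breakdown = as.list(x$error_breakdown))
}
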