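#' Match detected beats against reference beats
#'
#' One-to-one nearest matching within a tolerance: each reference beat is
#' paired with the closest unmatched detection no further than `tol_s` away.
#' Matched pairs count as true positives; unmatched references as false
#' negatives; unmatched detections as false positives.
#'
#' @param detected detected beat times, seconds (ascending).
#' @param reference ground-truth beat times, seconds (ascending).
#' @param tol_s matching tolerance, seconds.
#' @return list with `tp`, `fp`, `fn` counts and `pairs`, a data.frame of
#'   matched (reference, detected) times.
#' @export
match_beats <- function(detected, reference, tol_s) {
  used <- logical(length(detected))
  ref_m <- numeric(0); det_m <- numeric(0)
  for (r in reference) {
    if (!length(detected)) break
    dist <- abs(detected - r)
    dist[used] <- Inf
    j <- which.min(dist)
    if (is.finite(dist[j]) && dist[j] <= tol_s) {
      used[j] <- TRUE
      ref_m <- c(ref_m, r); det_m <- c(det_m, detected[j])
    }
  }
  list(tp = length(ref_m), fp = sum(!used), fn = length(reference) - length(ref_m),
       pairs = data.frame(reference = ref_m, detected = det_m))
}

eval_from_counts <- function(tp, fp, fn, tn = NA_integer_) {
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    acc = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_,
    acc_conventional = if (!is.na(tn)) (tp + tn) / (tp + tn + fp + fn) else NA_real_
  ), class = "eval_counts")
}

#' Detection and classification performance metrics
#'
#' Sensitivity `Se = TP / (TP + FN)`, positive predictivity
#' `+P = TP / (TP + FP)` and the accuracy form `Acc = TP / (TP + FP + FN)`,
#' which deliberately has no true-negative term (the form used throughout
#' this pipeline's evaluation); the conventional accuracy
#' `(TP + TN) / total` is reported alongside to avoid confusion.
#'
#' @param predictions predicted binary labels (0/1, logical, or factor).
#' @param labels reference binary labels of equal length.
#' @param positive the label value counted as positive (default 1).
#' @return object of class `eval_counts` with fields `tp`, `fp`, `fn`, `tn`,
#'   `se`, `ppv`, `acc`, `acc_conventional`.
#' @export
evaluate <- function(predictions, labels, positive = 1L) {
  if (length(predictions) == 0L) stopf("empty predictions")
  if (length(predictions) != length(labels))
    stopf("predictions (%d) and labels (%d) differ in length",
          length(predictions), length(labels))
  p <- predictions == positive
  l <- labels == positive
  eval_from_counts(tp = sum(p & l), fp = sum(p & !l), fn = sum(!p & l),
                   tn = sum(!p & !l))
}

#' Beat-detection metrics against reference beat times
#'
#' @param detected detected beat times, seconds.
#' @param reference reference beat times, seconds.
#' @param tol_s matching tolerance, seconds.
#' @return `eval_counts` object (TN undefined for event detection).
#' @export
evaluate_beats <- function(detected, reference, tol_s) {
  m <- match_beats(detected, reference, tol_s)
  eval_from_counts(m$tp, m$fp, m$fn)
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d%s\n", x$tp, x$fp, x$fn,
              if (!is.na(x$tn)) sprintf(" TN=%d", x$tn) else ""))
  cat(sprintf("Se=%.4f +P=%.4f Acc=%.4f%s\n", x$se, x$ppv, x$acc,
              if (!is.na(x$acc_conventional))
                sprintf(" (conventional accuracy %.4f)", x$acc_conventional)
              else ""))
  invisible(x)
}

#' Mean absolute interval error
#'
#' Mean of the absolute differences between detected DD intervals and
#' reference RR intervals, element by element.
#'
#' @param dd detected intervals, seconds.
#' @param rr reference intervals, same length.
#' @return mean absolute error in seconds.
#' @export
mean_abs_error <- function(dd, rr) {
  if (length(dd) != length(rr))
    stopf("interval sequences differ in length (%d vs %d)", length(dd), length(rr))
  if (length(dd) == 0L) stopf("empty interval sequences")
  mean(abs(dd - rr))
}

#' Interval error between matched beat sequences
#'
#' Matches detections to reference beats, forms the DD intervals between
#' consecutive matched detections and the RR intervals between the
#' corresponding reference beats, and returns their mean absolute
#' difference.
#'
#' @inheritParams evaluate_beats
#' @return mean absolute DD - RR error in seconds (`NA` with fewer than two
#'   matches).
#' @export
dd_interval_error <- function(detected, reference, tol_s) {
  m <- match_beats(detected, reference, tol_s)
  if (nrow(m$pairs) < 2L) return(NA_real_)
  p <- m$pairs[order(m$pairs$reference), ]
  mean_abs_error(diff(p$detected), diff(p$reference))
}
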