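#' Spatial average of ROI pixels in one frame
#'
#' The raw rPPG sample for a frame is the arithmetic mean of the pixel
#' intensities inside the region-of-interest mask; the result is independent
#' of pixel ordering.
#'
#' @param frame_pixels numeric matrix of pixel intensities.
#' @param mask logical matrix of the same dimensions; `TRUE` marks ROI pixels.
#' @return the mean in-mask intensity (scalar).
#' @export
spatial_average <- function(frame_pixels, mask) {
  if (!is.logical(mask)) stopf("mask must be logical")
  if (!identical(dim(frame_pixels), dim(mask)))
    stopf("frame (%s) and mask (%s) dimensions differ",
          paste(dim(frame_pixels), collapse = "x"),
          paste(dim(mask), collapse = "x"))
  if (!any(mask)) stopf("mask is empty: at least one ROI pixel is required")
  v <- frame_pixels[mask]
  if (!all(is.finite(v))) stopf("non-finite pixel value inside the ROI mask")
  mean(v)
}

#' Assemble a raw rPPG trace from per-frame means
#'
#' @param values per-frame mean intensities.
#' @param t start time of the first frame, seconds.
#' @param fs frame rate, frames per second; the frame interval is `1/fs`.
#' @return an object of class `raw_trace` with fields `values`, `t0`, `fs`,
#'   `tau` and `n`.
#' @export
assemble_trace <- function(values, t = 0, fs = 30) {
  check_number(fs, "fs", lower = 1e-12)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stopf("a trace needs at least 2 samples (got %d)", length(values))
  if (!all(is.finite(values))) stopf("trace values must be finite")
  structure(list(values = values, t0 = t, fs = fs, tau = 1 / fs,
                 n = length(values)),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("Raw rPPG trace: %d samples at %g frames/s (%.1f s from t=%g s)\n",
              x$n, x$fs, x$n / x$fs, x$t0))
  invisible(x)
}

#' Sliding analysis windows over a trace
#'
#' Yields windows of `window_s` seconds advanced by `hop_s` seconds, the
#' standard 30 s / 1 s sliding scheme of frame-rate rPPG analysis. The number
#' of windows is `floor((N - W) / H) + 1` for a window of W samples hopped by
#' H samples.
#'
#' @param trace a [assemble_trace()] object.
#' @param window_s window duration, seconds.
#' @param hop_s hop between window starts, seconds.
#' @return list of `raw_trace` windows, each carrying its own start time.
#' @export
trace_windows <- function(trace, window_s = 30, hop_s = 1) {
  stopifnot(inherits(trace, "raw_trace"))
  w <- as.integer(round(window_s * trace$fs))
  h <- as.integer(round(hop_s * trace$fs))
  if (h < 1L) stopf("hop_s too small: under one sample")
  if (trace$n < w)
    stopf("trace has %d samples but one %g s window needs %d (short by %d)",
          trace$n, window_s, w, w - trace$n)
  starts <- seq(1L, trace$n - w + 1L, by = h)
  lapply(starts, function(s)
    assemble_trace(trace$values[s:(s + w - 1L)],
                   t = trace$t0 + (s - 1L) / trace$fs, fs = trace$fs))
}

#' Select the ROI candidate with the best score
#'
#' Deterministic argmax selection among candidate masks (e.g. superpixels
#' scored by achromaticity); ties are broken by the lowest candidate index.
#'
#' @param candidate_masks list of candidate masks (any representation).
#' @param scores numeric score per candidate; at least one must be finite.
#' @return the winning candidate, with attributes `index` and `score`.
#' @export
select_roi <- function(candidate_masks, scores) {
  if (length(candidate_masks) == 0L) stopf("no ROI candidates supplied")
  if (length(scores) != length(candidate_masks))
    stopf("scores (%d) and candidates (%d) differ in length",
          length(scores), length(candidate_masks))
  if (!any(is.finite(scores))) stopf("no candidate has a finite score")
  i <- which.max(replace(scores, !is.finite(scores), -Inf))
  structure(candidate_masks[[i]], index = i, score = scores[i])
}
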