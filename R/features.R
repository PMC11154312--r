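# Model-input feature vectors. The composition of both vectors is a package
# convention (documented in the methods vignette): the upstream architecture
# fixes only the input lengths (1024 for the heart-rate model, 600 for the
# face model).

# Linear resampling of a vector to an exact length.
resample_linear <- function(v, n_out) {
  if (length(v) == 1L) return(rep(v, n_out))
  stats::approx(seq_along(v), v, n = n_out)$y
}

#' Per-second HRV feature track from beats
#'
#' For every whole second in the span of the beats, computes the
#' instantaneous heart rate (from the interpolated tachogram) plus SD and
#' LF/HF over a trailing sub-window. LF/HF is evaluated every `lfhf_step_s`
#' seconds and linearly interpolated onto the per-second grid (it varies
#' slowly and is the costly feature to compute).
#'
#' @param beat_times ascending beat times, seconds.
#' @param dd intervals (default `diff(beat_times)`).
#' @param sd_window_s trailing window for SD, seconds.
#' @param lfhf_window_s trailing window for LF/HF, seconds.
#' @param lfhf_step_s evaluation step for LF/HF, seconds.
#' @param cfg [spectral_config()] used inside the trailing LF/HF windows.
#' @return matrix with one row per second and columns `hr_bpm`, `sd_s`,
#'   `lf_hf`.
#' @export
hr_feature_track <- function(beat_times, dd = NULL, sd_window_s = 20,
                             lfhf_window_s = 40, lfhf_step_s = 4,
                             cfg = spectral_config(L = 128)) {
  if (is.null(dd)) dd <- diff(beat_times)
  span <- max(beat_times) - min(beat_times)
  need <- max(sd_window_s, lfhf_window_s) + 1
  if (span < need)
    stopf("feature track needs at least %g s of beats (got %.1f s)", need, span)
  tach <- build_tachogram(beat_times, dd, fs_out = cfg$fs)
  secs <- seq(min(beat_times) + max(sd_window_s, lfhf_window_s),
              max(beat_times), by = 1)
  hr <- 60 / stats::approx(tach$t, tach$y, xout = secs, rule = 2)$y
  end_t <- beat_times[-1]
  sdv <- vapply(secs, function(s) {
    w <- dd[end_t > s - sd_window_s & end_t <= s]
    if (length(w) < 2L) NA_real_ else hrv_time_domain(w)$sd_s
  }, numeric(1))
  lf_secs <- seq(secs[1], secs[length(secs)], by = lfhf_step_s)
  lfhf_pts <- vapply(lf_secs, function(s) {
    sel <- tach$t > s - lfhf_window_s & tach$t <= s
    if (sum(sel) < cfg$L) return(NA_real_)
    band_powers(welch_psd(tach$y[sel], cfg), cfg)$lf_hf
  }, numeric(1))
  lfhf <- if (length(lf_secs) > 1L)
    stats::approx(lf_secs, lfhf_pts, xout = secs, rule = 2)$y
  else rep(lfhf_pts, length(secs))
  out <- cbind(hr_bpm = hr, sd_s = sdv, lf_hf = lfhf)
  out[is.na(out)] <- 0
  out
}

#' Build the length-1024 heart-rate model input vector
#'
#' Concatenates the per-second heart-rate, SD and LF/HF tracks and linearly
#' resamples the concatenation to exactly 1024 values, so the first third of
#' the vector carries heart-rate slots, the middle third SD slots and the
#' last third LF/HF slots.
#'
#' @param track per-second feature matrix from [hr_feature_track()], or a
#'   beat-time vector (in which case the track is computed with defaults).
#' @param length_out output length (default 1024).
#' @return numeric vector of length `length_out`.
#' @export
build_hr_input <- function(track, length_out = 1024L) {
  if (!is.matrix(track)) track <- hr_feature_track(track)
  if (nrow(track) < 2L)
    stopf("insufficient history: at least 2 per-second samples required")
  v <- c(track[, "hr_bpm"], track[, "sd_s"], track[, "lf_hf"])
  resample_linear(v, length_out)
}

#' Build the length-600 face model input vector
#'
#' Averages the eye and mouth openness scores into 0.2 s bins over the
#' window (300 bins each for a 60 s window) and concatenates eye bins then
#' mouth bins into a 600-value vector.
#'
#' @param eye_openness,mouth_openness per-frame scores over one window.
#' @param length_out output length (default 600).
#' @return numeric vector of length `length_out`.
#' @export
build_face_input <- function(eye_openness, mouth_openness, length_out = 600L) {
  if (length(eye_openness) != length(mouth_openness))
    stopf("eye and mouth streams differ in length")
  half <- length_out %/% 2L
  c(resample_linear(bin_means(eye_openness, half), half),
    resample_linear(bin_means(mouth_openness, half), half))
}

# Mean over n_bins equal chunks (last chunk may be shorter).
bin_means <- function(v, n_bins) {
  idx <- ceiling(seq_along(v) / (length(v) / n_bins))
  as.numeric(tapply(v, pmin(idx, n_bins), mean))
}
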