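#' Time-domain HRV features
#'
#' Mean and standard deviation of the DD (inter-beat) interval sequence. The
#' SD uses the population form (divisor N), so `SD^2 * N` equals the sum of
#' squared deviations exactly.
#'
#' @param dd numeric interval sequence in seconds, length >= 2.
#' @return list with `mean_s`, `sd_s` and `n_intervals`.
#' @export
hrv_time_domain <- function(dd) {
  n <- length(dd)
  if (n < 2L) stopf("time-domain HRV needs at least 2 intervals (got %d)", n)
  m <- sum(dd) / n
  list(mean_s = m, sd_s = sqrt(sum((dd - m)^2) / n), n_intervals = n)
}

#' Resample the interval series onto a uniform tachogram grid
#'
#' Interpolates the (beat time, interval) pairs with a natural cubic spline
#' onto a uniform grid at `fs_out`, producing the evenly sampled tachogram
#' that spectral analysis requires (a PSD of unevenly spaced intervals is
#' otherwise undefined).
#'
#' @param beat_times ascending beat times, seconds.
#' @param dd intervals; `length(dd) = length(beat_times) - 1` (interval i is
#'   attached to the time of its closing beat), or equal length.
#' @param fs_out tachogram sampling rate, Hz (default 4).
#' @return list with `t` (grid times), `y` (interpolated intervals), `fs`.
#' @export
build_tachogram <- function(beat_times, dd = NULL, fs_out = 4) {
  if (is.null(dd)) {
    dd <- diff(beat_times)
    beat_times <- beat_times[-1]
  } else if (length(dd) == length(beat_times) - 1L) {
    beat_times <- beat_times[-1]
  } else if (length(dd) != length(beat_times)) {
    stopf("dd (%d) must have length(beat_times) (%d) or one fewer",
          length(dd), length(beat_times))
  }
  if (length(dd) < 4L) stopf("tachogram needs at least 4 beats")
  tt <- seq(beat_times[1], beat_times[length(beat_times)], by = 1 / fs_out)
  y <- stats::spline(beat_times, dd, xout = tt, method = "natural")$y
  list(t = tt, y = y, fs = fs_out)
}

#' Spectral analysis configuration
#'
#' @param fs tachogram sampling rate, Hz.
#' @param L Welch segment length, samples (divisible by 4).
#' @param window window function name (`"hamming"` or `"hann"`).
#' @param overlap `"quarter-step"` advances segments by L/4 (75% overlap
#'   between neighbours, the printed scheme); `"half"` uses the conventional
#'   L/2 step.
#' @param lf_band,hf_band LF and HF band edges, Hz (standard 0.04-0.15 and
#'   0.15-0.40).
#' @return a list of class `spectral_config`.
#' @export
spectral_config <- function(fs = 4, L = 256, window = c("hamming", "hann"),
                            overlap = c("quarter-step", "half"),
                            lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40)) {
  window <- match.arg(window)
  overlap <- match.arg(overlap)
  check_number(fs, "fs", lower = 1e-9)
  check_number(L, "L", lower = 4)
  if (L %% 4 != 0) stopf("segment length L=%d must be divisible by 4", L)
  if (!(lf_band[1] < lf_band[2] && lf_band[2] <= hf_band[1] &&
        hf_band[1] < hf_band[2]))
    stopf("LF and HF bands must be disjoint and ascending")
  structure(list(fs = fs, L = as.integer(L), window = window,
                 step = as.integer(if (overlap == "quarter-step") L / 4 else L / 2),
                 lf_band = lf_band, hf_band = hf_band),
            class = "spectral_config")
}

#' Split a series into overlapping Welch segments
#'
#' Segment i starts at `(i - 1) * step` (0-based) and spans L samples; only
#' fully contained segments are used, giving
#' `floor((N - L) / step) + 1` segments. With the quarter step,
#' consecutive segments share 3L/4 samples.
#'
#' @param y numeric series of length >= L.
#' @param cfg a [spectral_config()].
#' @return numeric matrix with one segment per row.
#' @export
welch_segments <- function(y, cfg) {
  stopifnot(inherits(cfg, "spectral_config"))
  n <- length(y)
  if (n < cfg$L) stopf("series length %d below segment length L=%d", n, cfg$L)
  starts <- seq(1L, n - cfg$L + 1L, by = cfg$step)
  t(vapply(starts, function(s) y[s:(s + cfg$L - 1L)], numeric(cfg$L)))
}

spectral_window <- function(cfg) {
  m <- seq_len(cfg$L) - 1L
  switch(cfg$window,
         hamming = 0.54 - 0.46 * cos(2 * pi * m / (cfg$L - 1L)),
         hann = 0.5 - 0.5 * cos(2 * pi * m / (cfg$L - 1L)))
}

#' Welch power spectral density estimate
#'
#' Averaged windowed periodograms over overlapping segments. Each segment's
#' periodogram is `|FFT(y_i * D)|^2 / (L U)` with the window-power
#' normalization `U = (1/L) sum D(m)^2`, which makes the estimate
#' asymptotically unbiased; segment periodograms are averaged and returned
#' one-sided as a density (power per Hz), so the integral over frequency
#' approximates the series variance.
#'
#' @param y numeric series (the tachogram). The mean is removed before
#'   estimation unless `demean = FALSE`.
#' @param cfg a [spectral_config()].
#' @param demean remove the series mean first (default `TRUE`).
#' @return list with `freq` (Hz) and `psd` (power per Hz), both of length
#'   `L/2 + 1`, plus `n_segments`.
#' @export
welch_psd <- function(y, cfg = spectral_config(), demean = TRUE) {
  stopifnot(inherits(cfg, "spectral_config"))
  if (demean) y <- y - mean(y)
  seg <- welch_segments(y, cfg)
  D <- spectral_window(cfg)
  U <- mean(D^2)
  L <- cfg$L
  half <- L %/% 2 + 1L
  acc <- numeric(half)
  for (i in seq_len(nrow(seg))) {
    sp <- Mod(stats::fft(seg[i, ] * D))^2 / (L * U)
    acc <- acc + sp[seq_len(half)]
  }
  p <- acc / nrow(seg)
  # one-sided density: double interior bins, scale to per-Hz
  p[2:(half - 1L)] <- 2 * p[2:(half - 1L)]
  list(freq = (seq_len(half) - 1L) * cfg$fs / L, psd = p / cfg$fs,
       n_segments = nrow(seg))
}

#' LF and HF band powers and their ratio
#'
#' Trapezoidal integrals of the PSD over the LF and HF bands. A zero HF
#' power yields an `Inf` ratio (flag), not an error.
#'
#' @param psd list with `freq` and `psd` (from [welch_psd()]).
#' @param cfg a [spectral_config()] carrying the band edges.
#' @return list with `lf`, `hf`, `lf_hf`.
#' @export
band_powers <- function(psd, cfg = spectral_config()) {
  stopifnot(inherits(cfg, "spectral_config"))
  if (max(psd$freq) < cfg$hf_band[2])
    stopf("PSD grid (max %g Hz) does not cover the HF band (to %g Hz)",
          max(psd$freq), cfg$hf_band[2])
  band_int <- function(band) {
    f <- psd$freq; p <- psd$psd
    sel <- f >= band[1] & f <= band[2]
    if (sum(sel) < 2L) return(0)
    fi <- f[sel]; pv <- p[sel]
    sum(diff(fi) * (utils::head(pv, -1) + utils::tail(pv, -1)) / 2)
  }
  lf <- band_int(cfg$lf_band)
  hf <- band_int(cfg$hf_band)
  list(lf = lf, hf = hf, lf_hf = if (hf > 0) lf / hf else Inf)
}

#' Full HRV feature set from detected beats
#'
#' Convenience wrapper: time-domain mean/SD of the intervals plus Welch
#' LF/HF on the resampled tachogram.
#'
#' @param beat_times ascending beat times, seconds.
#' @param dd intervals (default `diff(beat_times)`).
#' @param cfg a [spectral_config()].
#' @return list with `mean_s`, `sd_s`, `n_intervals`, `lf`, `hf`, `lf_hf`,
#'   and the `psd` list.
#' @export
hrv_features <- function(beat_times, dd = NULL, cfg = spectral_config()) {
  if (is.null(dd)) dd <- diff(beat_times)
  td <- hrv_time_domain(dd)
  tach <- build_tachogram(beat_times, dd, fs_out = cfg$fs)
  psd <- welch_psd(tach$y, cfg)
  bp <- band_powers(psd, cfg)
  c(td, bp, list(psd = psd))
}
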