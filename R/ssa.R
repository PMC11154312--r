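#' Embed a series into its Hankel trajectory matrix
#'
#' Builds the M x K trajectory matrix (K = N - M + 1) whose entry (i, j)
#' is `series[i + j - 1]`, the first step of singular spectrum analysis.
#'
#' @param series numeric series of length N.
#' @param M embedding window length in samples, 2 <= M <= N - 1.
#' @return numeric matrix of dimension M x (N - M + 1).
#' @export
ssa_embed <- function(series, M) {
  n <- length(series)
  if (M < 2 || M > n - 1)
    stopf("embedding window M=%d out of range [2, %d]", M, n - 1)
  K <- n - M + 1L
  outer(seq_len(M), seq_len(K), function(i, j) series[i + j - 1L])
}

#' Singular value decomposition of a trajectory matrix
#'
#' Decomposes A = U diag(sigma) V' with singular values in descending order;
#' sigma_i^2 equal the eigenvalues of A A'. A deterministic sign convention
#' is applied: the largest-magnitude entry of each left singular vector is
#' made positive.
#'
#' @param A trajectory matrix from [ssa_embed()].
#' @return list of class `ssa_decomposition`: `u`, `v`, `sigma`, `lambda`
#'   (= sigma^2), `M`, `K`, `n`.
#' @export
ssa_decompose <- function(A) {
  if (!all(is.finite(A))) stopf("trajectory matrix has non-finite entries")
  s <- tryCatch(svd(A), error = function(e)
    stopf("SVD of the trajectory matrix failed: %s", conditionMessage(e)))
  for (i in seq_along(s$d)) {
    j <- which.max(abs(s$u[, i]))
    if (s$u[j, i] < 0) {
      s$u[, i] <- -s$u[, i]
      s$v[, i] <- -s$v[, i]
    }
  }
  structure(list(u = s$u, v = s$v, sigma = s$d, lambda = s$d^2,
                 M = nrow(A), K = ncol(A), n = nrow(A) + ncol(A) - 1L),
            class = "ssa_decomposition")
}

#' @export
print.ssa_decomposition <- function(x, ...) {
  frac <- x$lambda / sum(x$lambda)
  cat(sprintf("SSA decomposition: M=%d, K=%d (N=%d)\n", x$M, x$K, x$n))
  cat(sprintf("  top singular values: %s\n",
              paste(signif(utils::head(x$sigma, 5), 4), collapse = ", ")))
  cat(sprintf("  energy in top 2 components: %.1f%%\n", 100 * sum(frac[1:2])))
  invisible(x)
}

# Elementary component matrix R_i = sigma_i u_i v_i'.
ssa_component_matrix <- function(dec, i) {
  dec$sigma[i] * tcrossprod(dec$u[, i], dec$v[, i])
}

#' Reconstruct a series from a trajectory-shaped matrix
#'
#' Diagonal (anti-diagonal) averaging: output element t is the mean of all
#' matrix entries whose row and column indices sum to t + 1, i.e. the mean
#' over each anti-diagonal. Reconstructing from the full trajectory matrix of
#' a series returns that series exactly.
#'
#' @param R an M x K matrix (component or sum of components).
#' @return numeric series of length M + K - 1.
#' @export
ssa_reconstruct <- function(R) {
  if (!is.matrix(R)) stopf("R must be a matrix")
  M <- nrow(R); K <- ncol(R)
  n <- M + K - 1L
  out <- numeric(n)
  cnt <- numeric(n)
  for (i in seq_len(M)) {
    idx <- i:(i + K - 1L)
    out[idx] <- out[idx] + R[i, ]
    cnt[idx] <- cnt[idx] + 1
  }
  out / cnt
}

#' Series reconstructed from selected SSA components
#'
#' @param dec an [ssa_decompose()] result.
#' @param indices component indices to sum (default: all).
#' @return numeric series of length `dec$n`.
#' @export
ssa_series <- function(dec, indices = seq_along(dec$sigma)) {
  stopifnot(inherits(dec, "ssa_decomposition"))
  if (length(indices) == 0L) return(numeric(dec$n))
  R <- dec$u[, indices, drop = FALSE] %*%
    (dec$sigma[indices] * t(dec$v[, indices, drop = FALSE]))
  ssa_reconstruct(R)
}

# Dominant non-DC frequency of a series, Hz.
dominant_frequency <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[seq_len(floor(n / 2) + 1L)]
  sp[1] <- 0
  (which.max(sp) - 1L) * fs / n
}

#' Select SSA components carrying the cardiac pulse
#'
#' A component is kept when the dominant discrete-Fourier frequency of its
#' reconstructed series lies inside the cardiac passband. An empty selection
#' is a valid outcome (flagged with a warning): it means no component looks
#' like pulse.
#'
#' @param dec an [ssa_decompose()] result.
#' @param fs sampling rate of the original series, Hz.
#' @param passband two-element numeric, default `c(0.8, 4)` Hz.
#' @return integer vector of selected component indices (possibly empty).
#' @export
select_pulse_components <- function(dec, fs, passband = c(0.8, 4)) {
  stopifnot(inherits(dec, "ssa_decomposition"))
  keep <- vapply(seq_along(dec$sigma), function(i) {
    if (dec$sigma[i] <= 1e-12 * dec$sigma[1]) return(FALSE)
    f <- dominant_frequency(ssa_series(dec, i), fs)
    f >= passband[1] && f <= passband[2]
  }, logical(1))
  idx <- which(keep)
  if (length(idx) == 0L)
    warnf("no SSA component has its dominant frequency in [%g, %g] Hz",
          passband[1], passband[2])
  idx
}

#' Moving-average filter
#'
#' Trailing moving mean over windows of L samples: output i is the mean of
#' `series[i .. i+L-1]`, giving N - L + 1 outputs.
#'
#' @param series numeric input of length N.
#' @param L window length in samples, 1 <= L <= N.
#' @return numeric series of length N - L + 1.
#' @export
moving_average <- function(series, L) {
  n <- length(series)
  if (L < 1 || L > n) stopf("moving-average window L=%d out of range [1, %d]", L, n)
  if (L == 1) return(series)
  cs <- cumsum(c(0, series))
  (cs[(L + 1L):(n + 1L)] - cs[seq_len(n - L + 1L)]) / L
}

# Centred moving-average baseline of the same length as the input, with
# shrinking windows at the edges. Used to detrend respiratory drift.
ma_baseline <- function(x, L) {
  n <- length(x)
  L <- min(max(1L, as.integer(L)), n)
  half <- (L - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (L - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Zero-phase Hamming-window FIR bandpass filter
#'
#' Designs a linear-phase FIR bandpass with a Hamming window and applies it
#' forward and backward (zero phase). The default 0.8-4 Hz passband spans
#' the plausible cardiac range (48-240 bpm).
#'
#' @param series numeric input.
#' @param fs sampling rate, Hz.
#' @param low,high passband edges, Hz; must satisfy 0 < low < high < fs/2.
#' @param taps_s FIR length in seconds of signal (default 3 s of taps).
#' @return filtered series, same length as the input.
#' @export
bandpass <- function(series, fs, low = 0.8, high = 4, taps_s = 3) {
  check_number(fs, "fs", lower = 1e-9)
  if (!(low > 0 && low < high && high < fs / 2))
    stopf("passband [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
          low, high, fs / 2)
  ord <- as.integer(round(taps_s * fs))
  ord <- ord + ord %% 2L  # even order -> odd, symmetric tap count
  b <- signal::fir1(ord, c(low, high) / (fs / 2), type = "pass",
                    window = signal::hamming(ord + 1L))
  as.numeric(signal::filtfilt(as.numeric(b), 1, series))
}

#' SSA-based pulse separation and filtering
#'
#' The full denoising chain: Hankel embedding, SVD, selection of components
#' whose dominant frequency lies in the cardiac passband, diagonal-averaging
#' reconstruction, moving-average detrending (the moving-average output is
#' used as a slow baseline and subtracted, removing respiratory-band
#' interference), and a zero-phase Hamming FIR bandpass. When no component
#' falls in the passband, the detrend + bandpass chain is applied to the
#' original series and the result is flagged.
#'
#' @param series numeric raw trace.
#' @param fs sampling rate, Hz.
#' @param M SSA embedding window in samples (default `round(fs)`, one
#'   cardiac cycle at 60 bpm).
#' @param passband cardiac passband, Hz.
#' @param ma_window_s moving-average window, seconds (default 1 s).
#' @param taps_s FIR length, seconds.
#' @param literal_ma if `TRUE`, the moving-average stage is applied as a
#'   plain low-pass (its output, shorter by L - 1 samples, is passed on)
#'   instead of being used as a subtracted baseline.
#' @return list of class `ssa_denoise`: `filtered`, `components` (selected
#'   indices), `decomposition`, `fs`, `fallback` (TRUE when no component was
#'   in band).
#' @export
ssa_denoise <- function(series, fs, M = round(fs), passband = c(0.8, 4),
                        ma_window_s = 1, taps_s = 3, literal_ma = FALSE) {
  A <- ssa_embed(series, as.integer(M))
  dec <- ssa_decompose(A)
  idx <- suppressWarnings(select_pulse_components(dec, fs, passband))
  fallback <- length(idx) == 0L
  g <- if (fallback) series else ssa_series(dec, idx)
  L <- max(1L, as.integer(round(ma_window_s * fs)))
  g <- if (literal_ma) moving_average(g, L) else g - ma_baseline(g, L)
  filtered <- bandpass(g, fs, passband[1], passband[2], taps_s)
  structure(list(filtered = filtered, components = idx, decomposition = dec,
                 fs = fs, fallback = fallback),
            class = "ssa_denoise")
}

#' @export
print.ssa_denoise <- function(x, ...) {
  cat(sprintf("SSA pulse separation: %d/%d components in band%s\n",
              length(x$components), length(x$decomposition$sigma),
              if (x$fallback) " (fallback: raw series filtered)" else ""))
  invisible(x)
}
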