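# Independent reference implementations used as oracles. These deliberately
# use plain loops / direct formulas, not the package's vectorized paths.

# Direct one-sided periodogram density (power per Hz).
ref_periodogram <- function(y, fs) {
  n <- length(y)
  y <- y - mean(y)
  half <- floor(n / 2) + 1L
  p <- Mod(stats::fft(y))^2 / n
  p <- p[seq_len(half)]
  p[2:(half - 1L)] <- 2 * p[2:(half - 1L)]
  list(freq = (seq_len(half) - 1L) * fs / n, psd = p / fs)
}

ref_band_ratio <- function(y, fs, lf = c(0.04, 0.15), hf = c(0.15, 0.40)) {
  pg <- ref_periodogram(y, fs)
  pow <- function(b) sum(pg$psd[pg$freq >= b[1] & pg$freq <= b[2]])
  pow(lf) / pow(hf)
}

# Loop-based 1-D CNN forward pass (valid convolutions, ReLU, FC, softmax).
ref_cnn_forward <- function(cfg, params, x) {
  a <- matrix(x, ncol = 1)  # [len, ch]
  for (li in seq_along(params$conv)) {
    k <- cfg$kernels[li]
    W <- params$conv[[li]]$W  # [k*ch_in, F]
    b <- params$conv[[li]]$b
    ch_in <- ncol(a)
    l_out <- nrow(a) - k + 1L
    out <- matrix(0, l_out, cfg$n_filters)
    for (t in seq_len(l_out)) {
      for (f in seq_len(cfg$n_filters)) {
        acc <- b[f]
        for (c in seq_len(ch_in)) for (kk in seq_len(k))
          acc <- acc + a[t + kk - 1L, c] * W[(c - 1L) * k + kk, f]
        out[t, f] <- max(acc, 0)
      }
    }
    a <- out
  }
  h <- as.vector(a)  # matches [len, ch] column-major flatten
  n_fc <- length(params$fc)
  for (i in seq_len(n_fc)) {
    h <- as.numeric(crossprod(params$fc[[i]]$W, h)) + params$fc[[i]]$b
    if (i < n_fc) h <- pmax(h, 0)
  }
  e <- exp(h - max(h))
  e / sum(e)
}

# Scalar-loop LSTM step, shared gate equations, both output variants.
ref_lstm_step <- function(params, x_t, h_prev, c_prev, variant = "printed") {
  hs <- params$hidden_size
  z <- c(h_prev, x_t)
  h <- numeric(hs); cs <- numeric(hs)
  for (i in seq_len(hs)) {
    gf <- 1 / (1 + exp(-(sum(params$Wf[i, ] * z) + params$bf[i])))
    gu <- 1 / (1 + exp(-(sum(params$Wu[i, ] * z) + params$bu[i])))
    cc <- tanh(sum(params$Wc[i, ] * z) + params$bc[i])
    go <- 1 / (1 + exp(-(sum(params$Wo[i, ] * z) + params$bo[i])))
    cs[i] <- gu * cc + gf * c_prev[i]
    h[i] <- if (variant == "printed") go * cs[i] else go * tanh(cs[i])
  }
  list(h = h, c = cs)
}

# Anti-diagonal averaging by explicit index search.
ref_diag_average <- function(R) {
  M <- nrow(R); K <- ncol(R); n <- M + K - 1L
  vapply(seq_len(n), function(t) {
    vals <- c()
    for (i in seq_len(M)) for (j in seq_len(K))
      if (i + j - 1L == t) vals <- c(vals, R[i, j])
    mean(vals)
  }, numeric(1))
}

# A clean pulse train plus ground truth, shared across detector tests.
make_pulse_fixture <- function(bpm, duration_s = 30, fs = 30, seed = 1,
                               jitter_sd_s = 0, pulse_width_s = NULL) {
  rr <- simulate_rr_series(rr_sim_config(
    duration_s = duration_s, mean_hr_bpm = bpm, lf_amp_s = 0, hf_amp_s = 0,
    jitter_sd_s = jitter_sd_s, seed = seed))
  pw <- pulse_width_s %||% min(0.5, 0.8 * 60 / bpm)
  x <- render_pulse_waveform(rr$beat_times,
                             pulse_sim_config(fs_hz = fs, pulse_width_s = pw))
  list(x = x, beat_times = rr$beat_times, intervals = rr$intervals, fs = fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
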