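test_that("time-domain features use the population SD as printed", {
  td <- hrv_time_domain(rep(1, 10))
  expect_identical(td$mean_s, 1)
  expect_identical(td$sd_s, 0)
  td <- hrv_time_domain(c(0.8, 1.0, 1.2))
  expect_equal(td$mean_s, 1)
  expect_equal(td$sd_s, sqrt(0.08 / 3), tolerance = 1e-15)
  # divisor-N identity: SD^2 * N equals the sum of squared deviations
  dd <- c(0.9, 1.05, 0.84, 1.11, 0.97)
  td <- hrv_time_domain(dd)
  expect_equal(td$sd_s^2 * 5, sum((dd - mean(dd))^2), tolerance = 1e-15)
  # translation invariance
  td2 <- hrv_time_domain(dd + 0.3)
  expect_equal(td2$mean_s, td$mean_s + 0.3)
  expect_equal(td2$sd_s, td$sd_s)
  expect_error(hrv_time_domain(1), "at least 2")
})

test_that("the tachogram preserves constant series and modulation frequency", {
  bt <- c(0, cumsum(rep(1, 40)))
  tach <- build_tachogram(bt, fs_out = 4)
  expect_true(all(abs(tach$y - 1) < 1e-9))
  expect_equal(unique(round(diff(tach$t), 12)), 0.25)
  # 0.1 Hz interval modulation shows up as the dominant tachogram frequency
  rr <- simulate_rr_series(rr_sim_config(duration_s = 200, lf_amp_s = 0.05,
                                         hf_amp_s = 0, hf_freq_hz = 0.25,
                                         seed = 2))
  tach <- build_tachogram(rr$beat_times, fs_out = 4)
  pg <- ref_periodogram(tach$y, 4)
  expect_equal(pg$freq[which.max(pg$psd)], 0.1, tolerance = 0.02)
  # mean preserved within 1%
  expect_lt(abs(mean(tach$y) - mean(rr$intervals)) / mean(rr$intervals), 0.01)
  expect_error(build_tachogram(c(0, 1, 2)), "at least 4")
})

test_that("Welch segmentation counts fully contained segments", {
  cfg <- spectral_config(fs = 4, L = 256)
  expect_identical(cfg$step, 64L)
  seg <- welch_segments(rnorm(1024), cfg)
  expect_identical(nrow(seg), 13L)   # floor((1024 - 192)/64)
  expect_identical(ncol(seg), 256L)
  # N = L: exactly one segment
  expect_identical(nrow(welch_segments(rnorm(256), cfg)), 1L)
  # consecutive segments share 3L/4 samples
  y <- seq_len(512)
  seg <- welch_segments(y, cfg)
  expect_identical(seg[1, 65:256], seg[2, 1:192])
  expect_error(welch_segments(rnorm(100), cfg), "below segment length")
  expect_error(spectral_config(L = 130), "divisible by 4")
})

test_that("Welch PSD is Parseval-consistent and localizes sinusoids", {
  cfg <- spectral_config(fs = 4, L = 256)
  set.seed(11)
  y <- rnorm(4096)
  w <- welch_psd(y, cfg)
  expect_true(all(w$psd >= 0))
  df <- w$freq[2] - w$freq[1]
  expect_lt(abs(sum(w$psd) * df - stats::var(y)) / stats::var(y), 0.1)
  # pure 0.1 Hz sinusoid: argmax bin at 0.1 Hz
  t <- (0:2047) / 4
  w2 <- welch_psd(sin(2 * pi * 0.1 * t), cfg)
  expect_lt(abs(w2$freq[which.max(w2$psd)] - 0.1), df)
  # all-zero input: all-zero PSD
  expect_true(all(welch_psd(rep(0, 512), cfg)$psd == 0))
})

test_that("band powers recover closed-form sinusoid ratios", {
  cfg <- spectral_config(fs = 4, L = 256)
  t <- (0:4095) / 4
  # equal amplitudes at 0.1 and 0.25 Hz: ratio ~ 1
  y <- sin(2 * pi * 0.1 * t) + sin(2 * pi * 0.25 * t)
  bp <- band_powers(welch_psd(y, cfg), cfg)
  expect_equal(bp$lf_hf, 1, tolerance = 0.1)
  # 2:1 amplitudes: power ratio ~ 4
  y <- 2 * sin(2 * pi * 0.1 * t) + sin(2 * pi * 0.25 * t)
  bp <- band_powers(welch_psd(y, cfg), cfg)
  expect_equal(bp$lf_hf, 4, tolerance = 0.4)
  # HF-free signal flags an infinite ratio rather than erroring
  y <- sin(2 * pi * 0.1 * t)
  bp <- band_powers(list(freq = c(0.05, 0.1, 0.2, 0.3, 0.45),
                         psd = c(1, 1, 0, 0, 0)), cfg)
  expect_identical(bp$lf_hf, Inf)
  expect_error(band_powers(list(freq = c(0, 0.1), psd = c(1, 1)), cfg),
               "does not cover")
})

test_that("simulated RR ground truth is recovered by the spectral chain", {
  rr <- simulate_rr_series(rr_sim_config(duration_s = 300, lf_amp_s = 0.06,
                                         hf_amp_s = 0.03, jitter_sd_s = 0,
                                         seed = 21))
  f <- hrv_features(rr$beat_times, cfg = spectral_config(L = 256))
  expect_lt(abs(f$lf_hf - rr$truth$true_lf_over_hf) / rr$truth$true_lf_over_hf,
            0.15)
})

test_that("a fixed-seed AR(1) Welch estimate tracks a long periodogram oracle", {
  set.seed(33)
  n <- 8192
  y <- as.numeric(stats::arima.sim(list(ar = 0.7), n))
  cfg <- spectral_config(fs = 4, L = 256)
  w <- welch_psd(y, cfg)
  pg <- ref_periodogram(y, 4)
  # compare band-integrated power in LF and HF between the two estimators
  for (band in list(c(0.04, 0.15), c(0.15, 0.40))) {
    pw <- sum(w$psd[w$freq >= band[1] & w$freq <= band[2]]) *
      (w$freq[2] - w$freq[1])
    pp <- sum(pg$psd[pg$freq >= band[1] & pg$freq <= band[2]]) *
      (pg$freq[2] - pg$freq[1])
    expect_lt(abs(pw - pp) / pp, 0.2)
  }
})
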