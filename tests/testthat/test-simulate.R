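test_that("RR simulation honours the zero-modulation and analytic-ratio cases", {
  # zero modulation at 60 bpm: 30 intervals of exactly 1 s
  rr <- simulate_rr_series(rr_sim_config(duration_s = 30, mean_hr_bpm = 60,
                                         lf_amp_s = 0, hf_amp_s = 0))
  expect_length(rr$intervals, 30L)
  expect_equal(rr$intervals, rep(1, 30))
  expect_equal(diff(rr$beat_times), rr$intervals)

  # equal amplitudes give analytic ratio 1
  rr <- simulate_rr_series(rr_sim_config(lf_amp_s = 0.05, hf_amp_s = 0.05))
  expect_identical(rr$truth$true_lf_over_hf, 1)

  # 2:1 amplitudes give ratio 4, and a direct periodogram on the rendered
  # tachogram recovers it within 15%
  rr <- simulate_rr_series(rr_sim_config(duration_s = 300, lf_amp_s = 0.06,
                                         hf_amp_s = 0.03, jitter_sd_s = 0,
                                         seed = 3))
  expect_identical(rr$truth$true_lf_over_hf, 4)
  tach <- build_tachogram(rr$beat_times, fs_out = 4)
  expect_lt(abs(ref_band_ratio(tach$y, 4) - 4) / 4, 0.15)
})

test_that("RR simulation is deterministic and rejects bad configurations", {
  cfg <- rr_sim_config(duration_s = 60, jitter_sd_s = 0.02, seed = 9L)
  expect_identical(simulate_rr_series(cfg), simulate_rr_series(cfg))
  expect_error(rr_sim_config(mean_hr_bpm = 20), "mean_hr_bpm")
  expect_error(rr_sim_config(lf_freq_hz = 0.3, hf_freq_hz = 0.2), "below")
  # amplitudes large enough to push an interval non-positive are rejected
  expect_error(
    simulate_rr_series(rr_sim_config(mean_hr_bpm = 180, lf_amp_s = 0.3,
                                     hf_amp_s = 0.3)),
    "implausibly small")
})

test_that("pulse rendering places peaks at beat times", {
  cfg <- pulse_sim_config(fs_hz = 30, pulse_width_s = 0.5)
  # empty input renders an all-zero trace
  expect_true(all(render_pulse_waveform(numeric(0), cfg) == 0))
  # one beat at 1.0 s peaks at 0-based sample index 30
  x <- render_pulse_waveform(1.0, cfg)
  expect_identical(which.max(x) - 1L, 30L)
  # 60 bpm for 30 s: exactly 30 local maxima above half pulse height
  x <- render_pulse_waveform(seq(1, 30), cfg, duration_s = 31)
  n <- length(x)
  is_peak <- x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
    x[2:(n - 1)] > 0.5
  expect_identical(sum(is_peak), 30L)
  # overlapping pulses warn but still render
  expect_warning(
    render_pulse_waveform(c(1, 1.2), pulse_sim_config(pulse_width_s = 0.5)),
    "overlap")
})

test_that("eye-state streams realize the requested fractions exactly", {
  st <- simulate_eye_state_stream(eye_state_sim_config(closed_fraction = 0))
  expect_identical(st$truth$true_perclos, 0)

  st <- simulate_eye_state_stream(eye_state_sim_config(
    fps = 20, window_s = 60, closed_fraction = 0.25, yawn_fraction = 0.10))
  expect_identical(nrow(st$frames), 1200L)
  expect_identical(sum(st$frames$eye_state == "closed"), 300L)
  expect_identical(st$truth$true_perclos, 300 / 1200)
  expect_identical(st$truth$true_yawn_rate, 0.10)
  expect_identical(sum(st$frames$mouth_state == "yawn"), 120L)
  # ground truth equals realized label fractions exactly, for many configs
  for (cf in c(0.07, 0.33, 0.5)) {
    s2 <- simulate_eye_state_stream(eye_state_sim_config(
      closed_fraction = cf, seed = round(100 * cf)))
    expect_identical(mean(s2$frames$eye_state == "closed"),
                     s2$truth$true_perclos)
  }
  expect_error(eye_state_sim_config(fps = 20, window_s = 60.025), "integer")
})

test_that("ROI frame simulation round-trips the trace through spatial_average", {
  mask <- matrix(FALSE, 6, 6); mask[2:4, 3:5] <- TRUE
  # constant fill: every in-mask pixel equals the trace value
  fr <- simulate_roi_frames(5.0, mask)
  expect_true(all(fr[[1]][mask] == 5.0))
  # zero-mean perturbation keeps the in-mask mean exact
  fr <- simulate_roi_frames(2.0, mask, perturb_sd = 0.5, seed = 4)
  expect_equal(mean(fr[[1]][mask]), 2.0, tolerance = 1e-12)
  # full round trip over a waveform
  tr <- sin(seq(0, 4, length.out = 25))
  fr <- simulate_roi_frames(tr, mask, perturb_sd = 0.3, seed = 5)
  rec <- vapply(fr, spatial_average, numeric(1), mask = mask)
  expect_equal(rec, tr, tolerance = 1e-12)
  expect_error(simulate_roi_frames(1, matrix(FALSE, 2, 2)), "empty")
})

test_that("sessions are reproducible and survive a disk round trip", {
  s1 <- simulate_session(preset = "fatigue", n_windows = 2, seed = 5)
  s2 <- simulate_session(preset = "fatigue", n_windows = 2, seed = 5)
  expect_identical(s1, s2)
  expect_identical(s1$truth$labels, c(1L, 1L))
  dir <- withr::local_tempdir()
  write_session(s1, dir)
  s3 <- read_session(dir)
  expect_equal(s3$trace$value, s1$trace$value)
  expect_identical(nrow(s3$frames), nrow(s1$frames))
  expect_equal(s3$truth$labels, s1$truth$labels)
})
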