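test_that("five-point derivative is exact for low-degree polynomials", {
  expect_equal(five_point_derivative(rep(3, 10)), rep(0, 10))
  i <- 1:20
  expect_equal(five_point_derivative(i)[3:18], rep(1, 16))
  expect_equal(five_point_derivative(i^2)[3:18], 2 * i[3:18])
  # degree-4 exactness on interior points
  p <- 0.5 * i^4 - i^3 + 2 * i
  expect_equal(five_point_derivative(p)[3:18], 2 * i[3:18]^3 - 3 * i[3:18]^2 + 2)
  expect_error(five_point_derivative(1:4), "at least 5")
})

test_that("normalization and Shannon energy behave per their formulas", {
  expect_equal(normalize_signal(c(2, -4)), c(0.5, -1))
  v <- c(-1, 0.25, 1)
  expect_identical(normalize_signal(v), v)       # idempotent
  expect_identical(sign(normalize_signal(c(3, -9, 6))), c(1, -1, 1))
  expect_error(normalize_signal(c(0, 0)), "all-zero")

  expect_identical(shannon_energy(0), 0)
  expect_identical(shannon_energy(1), 0)
  expect_equal(shannon_energy(exp(-1 / 2)), exp(-1))
  x <- seq(-1, 1, by = 0.01)
  e <- shannon_energy(x)
  expect_true(all(e >= 0))
  expect_lte(max(e), exp(-1) + 1e-12)
  expect_error(shannon_energy(c(0.5, 1.2)), "normalize")
})

test_that("window integration uses the rounded sample count", {
  # 0.15 s at 200 Hz is the worked 30-sample window
  expect_identical(as.integer(round(0.15 * 200)), 30L)
  e <- c(rep(0, 50), 1, rep(0, 50))
  env <- window_integrate(e, 100, 0.15)  # 15-sample centred mean
  expect_equal(max(env), 1 / 15)
  expect_identical(sum(env > 0), 15L)
  expect_equal(sum(env), 1, tolerance = 1e-12)   # mass preserved
  expect_error(window_integrate(rep(0, 5), 100, 0.15), "longer than the signal")
})

test_that("threshold initialization follows the max/3 and mean/2 rules", {
  fs <- 10
  env <- rep(0, 60)
  env[c(10, 25)] <- c(4, 8)   # two candidate peaks in the first 3 s
  st <- init_thresholds(env, fs)
  expect_equal(st$ST, 8 / 3)
  expect_equal(st$NT, 3)      # mean(4, 8) / 2
  expect_equal(st$T1, st$NT + (st$ST - st$NT) / 4)
  expect_equal(st$T2, st$T1 / 2)
  # ST = NT collapse: T1 = NT
  st2 <- rppgfatigue:::new_detector_state(ST = 2, NT = 2)
  expect_equal(st2$T1, 2)
  expect_error(init_thresholds(rep(0, 60), fs), "no candidate peaks")
  expect_error(init_thresholds(env[1:10], fs), "at least 3")
})

test_that("threshold updates keep the dual-threshold algebra exact", {
  st <- rppgfatigue:::new_detector_state(ST = 0.8, NT = 0.2)
  expect_equal(st$T1, 0.35)
  expect_equal(st$T2, 0.175)
  # signal update: ST' = DP/8 + 7 ST/8
  st2 <- update_thresholds(st, 1.6, TRUE)
  expect_equal(st2$ST, 0.9)
  # fixed point: DP = ST leaves ST unchanged
  st3 <- update_thresholds(st, st$ST, TRUE)
  expect_equal(st3$ST, st$ST)
  # geometric convergence with ratio 7/8 under constant DP
  s <- rppgfatigue:::new_detector_state(ST = 2, NT = 0.1)
  dp <- 0.4
  for (k in 1:12) {
    prev <- s$ST
    s <- update_thresholds(s, dp, TRUE)
    expect_equal(s$ST - dp, (prev - dp) * 7 / 8, tolerance = 1e-14)
    expect_identical(s$T1, s$NT + (s$ST - s$NT) / 4)
    expect_identical(s$T2, s$T1 / 2)
  }
})

test_that("search-back recovers a sub-T1 super-T2 peak inside a long gap", {
  # constructed envelope: beats at 1 s intervals, one 2 s gap holding a
  # small hump between T2 and T1
  fs <- 10
  env <- rep(0.001, 140)
  beat_pos <- c(seq(5, 65, by = 10), seq(85, 135, by = 10))
  env[beat_pos] <- 1
  env[75] <- 0.2   # the missed beat
  st <- rppgfatigue:::new_detector_state(ST = 1, NT = 0.05)
  st$dd_buffer <- rep(1, 8)
  expect_gt(st$T1, 0.2)
  expect_lt(st$T2, 0.2)
  sb <- searchback_scan(st, env, gap = c(65, 85))
  expect_identical(sb$peak, 75L)
  # recovery applies the fast refresh ST' = DP/4 + 3 ST/4
  expect_equal(sb$state$ST, 0.2 / 4 + 3 * 1 / 4)
  # nothing above T2 in the gap: no recovery, state untouched
  env[75] <- st$T2 / 2
  sb2 <- searchback_scan(st, env, gap = c(65, 85))
  expect_null(sb2$peak)
  expect_identical(sb2$state$ST, st$ST)
  expect_error(searchback_scan(rppgfatigue:::new_detector_state(1, 0.1),
                               env, c(65, 85)), "DD buffer")
})

test_that("detect_beats nails clean trains and enforces the refractory period", {
  fx <- make_pulse_fixture(60)
  b <- detect_beats(fx$x, fx$fs)
  truth <- fx$beat_times[fx$beat_times >= 3]
  ev <- evaluate_beats(b$peak_times, truth, 1 / 30 + 1e-9)
  expect_identical(ev$se, 1)
  expect_identical(ev$ppv, 1)
  expect_true(all(b$dd_intervals >= 0.2))
  expect_true(all(diff(b$peak_times) > 0))
  # threshold algebra holds after every recorded update
  tt <- b$threshold_trace
  expect_equal(tt$T1, tt$NT + (tt$ST - tt$NT) / 4, tolerance = 1e-14)
  expect_equal(tt$T2, tt$T1 / 2, tolerance = 1e-14)
  # determinism
  expect_identical(detect_beats(fx$x, fx$fs)$peak_times, b$peak_times)
})

test_that("deeply attenuated beats are recovered through search-back", {
  bt <- 0:30
  amps <- rep(1, 31)
  att <- seq(6, 26, by = 5)      # away from the ends
  amps[att] <- 0.12
  x <- render_pulse_waveform(bt, pulse_sim_config(fs_hz = 30, pulse_width_s = 0.5),
                             amplitudes = amps)
  b <- detect_beats(x, 30)
  m <- match_beats(b$peak_times, bt[att], 0.1)
  expect_identical(m$fn, 0L)
  expect_gte(sum(b$provenance == "searchback"), length(att) - 1L)
  # overall detection still clean
  ev <- evaluate_beats(b$peak_times, bt[bt >= 3], 0.1)
  expect_identical(ev$ppv, 1)
})

test_that("candidate peaks inside the refractory period are dropped", {
  # two envelope humps 150 ms apart must yield a single beat
  fs <- 100
  t <- (0:499) / fs
  x <- exp(-((t - 2.0) / 0.03)^2) + 0.9 * exp(-((t - 2.15) / 0.03)^2) +
    exp(-((t - 1.0) / 0.03)^2) + exp(-((t - 3.0) / 0.03)^2) +
    exp(-((t - 4.0) / 0.03)^2)
  b <- detect_beats(x, fs, include_init = TRUE)
  hits <- b$peak_times[b$peak_times > 1.8 & b$peak_times < 2.4]
  expect_length(hits, 1L)
})
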