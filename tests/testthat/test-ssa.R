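test_that("trajectory embedding is Hankel with the printed indexing", {
  A <- ssa_embed(c(1, 2, 3, 4), 2)
  expect_identical(A, matrix(c(1, 2, 2, 3, 3, 4), 2, 3))
  # boundary M = N - 1 gives a 2-column matrix
  expect_identical(ncol(ssa_embed(1:5, 4)), 2L)
  # Hankel structure: entry (i, j) depends only on i + j
  x <- rnorm(20)
  A <- ssa_embed(x, 7)
  for (s in 2:(nrow(A) + ncol(A))) {
    i <- pmax(1, s - ncol(A)):pmin(nrow(A), s - 1)
    expect_true(all(A[cbind(i, s - i)] == x[s - 1]))
  }
  expect_error(ssa_embed(1:4, 1), "out of range")
  expect_error(ssa_embed(1:4, 4), "out of range")
})

test_that("SSA decomposition matches eigen structure and reconstructs", {
  # constant series embeds to a rank-1 matrix
  dec <- ssa_decompose(ssa_embed(rep(3, 10), 4))
  expect_lt(dec$sigma[2] / dec$sigma[1], 1e-12)
  # pure sinusoid: top 2 components carry > 99% of the squared spectrum
  x <- sin(2 * pi * 1.5 * (0:199) / 30)
  dec <- ssa_decompose(ssa_embed(x, 30))
  expect_gt(sum(dec$lambda[1:2]) / sum(dec$lambda), 0.99)
  # sum of all component matrices reconstructs A
  A <- ssa_embed(rnorm(40), 10)
  dec <- ssa_decompose(A)
  R <- Reduce(`+`, lapply(seq_along(dec$sigma), function(i)
    rppgfatigue:::ssa_component_matrix(dec, i)))
  expect_lt(max(abs(R - A)), 1e-10)
  # sigma^2 equal the eigenvalues of A A^T (independent eigensolver)
  ev <- eigen(A %*% t(A), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(dec$sigma, sqrt(pmax(ev, 0)), tolerance = 1e-12)
})

test_that("diagonal averaging inverts embedding and matches the naive oracle", {
  expect_identical(ssa_reconstruct(matrix(c(1, 2, 2, 3), 2, 2)), c(1, 2, 3))
  expect_identical(ssa_reconstruct(matrix(0, 3, 4)), rep(0, 6))
  set.seed(1)
  R <- matrix(rnorm(15), 3, 5)
  expect_equal(ssa_reconstruct(R), ref_diag_average(R), tolerance = 1e-14)
  # full round trip: series -> embed -> decompose -> all components -> series
  x <- rnorm(60)
  dec <- ssa_decompose(ssa_embed(x, 12))
  expect_equal(ssa_series(dec), x, tolerance = 1e-10)
})

test_that("component selection keeps cardiac-band components only", {
  t <- (0:599) / 30
  x <- sin(2 * pi * 1.5 * t) + 2 * sin(2 * pi * 0.2 * t)
  dec <- ssa_decompose(ssa_embed(x, 30))
  idx <- select_pulse_components(dec, 30)
  expect_gt(length(idx), 0)
  freqs <- vapply(idx, function(i)
    rppgfatigue:::dominant_frequency(ssa_series(dec, i), 30), numeric(1))
  expect_true(all(freqs >= 0.8 & freqs <= 4))
  # the selected set reconstructs the 1.5 Hz part, not the drift
  g <- ssa_series(dec, idx)
  expect_gt(cor(g, sin(2 * pi * 1.5 * t)), 0.97)
  expect_lt(abs(cor(g, 2 * sin(2 * pi * 0.2 * t))), 0.2)
  # all-drift signal: empty selection with a warning
  xd <- sin(2 * pi * 0.2 * t)
  expect_warning(
    idx0 <- select_pulse_components(ssa_decompose(ssa_embed(xd, 30)), 30),
    "dominant frequency")
  expect_length(idx0, 0L)
  # pure in-band sinusoid: selection carries >= 99% of the energy
  xs <- sin(2 * pi * 1.5 * t)
  dec2 <- ssa_decompose(ssa_embed(xs, 30))
  idx2 <- select_pulse_components(dec2, 30)
  expect_gte(sum(dec2$lambda[idx2]) / sum(dec2$lambda), 0.99)
})

test_that("moving average matches the windowed-mean oracle and is linear", {
  expect_equal(moving_average(c(1, 2, 3, 4), 2), c(1.5, 2.5, 3.5))
  expect_equal(moving_average(rep(7, 9), 4), rep(7, 6))
  x <- rnorm(30)
  expect_identical(moving_average(x, 1), x)
  # oracle: explicit window means
  L <- 5
  expect_equal(moving_average(x, L),
               vapply(1:(30 - L + 1), function(i) mean(x[i:(i + L - 1)]),
                      numeric(1)))
  # linearity
  y <- rnorm(30)
  expect_equal(moving_average(2 * x + 3 * y, L),
               2 * moving_average(x, L) + 3 * moving_average(y, L),
               tolerance = 1e-12)
  expect_error(moving_average(x, 31), "out of range")
})

test_that("bandpass passes the cardiac band and rejects drift and DC", {
  fs <- 30
  t <- (0:899) / fs
  # constant input is annihilated (away from filtfilt edge transients)
  expect_lt(max(abs(bandpass(rep(1, 900), fs)[150:750])), 0.01)
  # 1.5 Hz passes at unit gain (within 5% RMS)
  x <- sin(2 * pi * 1.5 * t)
  mid <- 150:750
  expect_lt(abs(sqrt(mean(bandpass(x, fs)[mid]^2)) / sqrt(mean(x[mid]^2)) - 1),
            0.05)
  # 0.2 Hz respiration attenuated by >= 20 dB
  xr <- sin(2 * pi * 0.2 * t)
  expect_lt(sqrt(mean(bandpass(xr, fs)[mid]^2)) / sqrt(mean(xr[mid]^2)), 0.1)
  expect_error(bandpass(x, fs, low = 0.8, high = 16), "Nyquist")
})

test_that("the denoising pipeline recovers the pulse from drift and noise", {
  fx <- make_pulse_fixture(66, duration_s = 40, seed = 8)
  clean <- fx$x
  set.seed(8)
  noisy <- clean +
    0.3 * sin(2 * pi * 0.2 * (seq_along(clean) - 1) / 30) +
    stats::rnorm(length(clean), 0, sqrt(mean((clean - mean(clean))^2) / 10))
  den <- ssa_denoise(noisy, 30)
  expect_false(den$fallback)
  expect_gt(cor(den$filtered, clean - mean(clean)), 0.9)
  # literal moving-average mode reproduces the printed trailing-mean output
  den2 <- ssa_denoise(noisy, 30, literal_ma = TRUE)
  expect_length(den2$filtered, length(noisy) - 30 + 1)
})
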