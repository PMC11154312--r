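# Model unit tests use deliberately small architectures; the full printed
# architectures are exercised by the acceptance suite.

test_that("CNN forward pass matches an independent loop-based implementation", {
  cfg <- cnn_config(48L, 6L, c(7L, 3L), c(10L), dropout = 0)
  params <- cnn_init(cfg, seed = 4)
  set.seed(7)
  for (rep in 1:3) {
    x <- rnorm(48)
    expect_equal(as.numeric(forward_cnn(cfg, params, x)),
                 ref_cnn_forward(cfg, params, x), tolerance = 1e-10)
  }
})

test_that("CNN probabilities are normalized and zero weights give 0.5/0.5", {
  cfg <- cnn_config(32L, 3L, c(5L), c(6L), dropout = 0)
  params <- cnn_init(cfg, seed = 1)
  zero <- rapply(params, function(p) p * 0, how = "replace")
  expect_equal(as.numeric(forward_cnn(cfg, zero, rnorm(32))), c(0.5, 0.5))
  set.seed(2)
  p <- forward_cnn(cfg, params, matrix(rnorm(5 * 32), 5))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_error(forward_cnn(cfg, params, rnorm(31)), "does not match")
})

test_that("CNN training separates an easy synthetic problem deterministically", {
  cfg <- cnn_config(40L, 4L, c(5L, 3L), c(12L), dropout = 0.2)
  set.seed(10)
  n <- 60
  y <- rep(0:1, each = n / 2)
  x <- t(vapply(y, function(lab) {
    f <- if (lab == 0) 2 else 5
    sin(2 * pi * f * (0:39) / 40) + rnorm(40, 0, 0.3)
  }, numeric(40)))
  m1 <- fit_cnn(x, y, cfg, epochs = 25, batch_size = 16, seed = 3)
  m2 <- fit_cnn(x, y, cfg, epochs = 25, batch_size = 16, seed = 3)
  expect_identical(m1$params, m2$params)   # deterministic training
  set.seed(11)
  yt <- rep(0:1, 20)
  xt <- t(vapply(yt, function(lab) {
    f <- if (lab == 0) 2 else 5
    sin(2 * pi * f * (0:39) / 40) + rnorm(40, 0, 0.3)
  }, numeric(40)))
  expect_gte(mean(predict(m1, xt, type = "class") == yt), 0.95)
  # loss broadly decreases over training
  expect_lt(mean(utils::tail(m1$history, 3)), mean(utils::head(m1$history, 3)))
})

test_that("lstm_step matches the printed equations and a reference cell", {
  p <- lstm_init(3, 4, seed = 5)
  zero <- p
  for (nm in c("Wf", "Wu", "Wc", "Wo")) zero[[nm]] <- zero[[nm]] * 0
  for (nm in c("bf", "bu", "bc", "bo")) zero[[nm]] <- zero[[nm]] * 0
  # all-zero parameters: gates 0.5, candidate 0 -> h = 0, c = 0 from rest
  st <- lstm_step(zero, rep(0, 3), rep(0, 4), rep(0, 4))
  expect_equal(st$h, rep(0, 4))
  expect_equal(st$c, rep(0, 4))
  # c_prev = 1: c = 0.5, printed output h = go * c = 0.25
  st <- lstm_step(zero, rep(0, 3), rep(0, 4), rep(1, 4))
  expect_equal(st$c, rep(0.5, 4))
  expect_equal(st$h, rep(0.25, 4))
  # standard variant applies tanh to the cell state
  st2 <- lstm_step(zero, rep(0, 3), rep(0, 4), rep(1, 4), variant = "standard")
  expect_equal(st2$h, rep(0.5 * tanh(0.5), 4))
  # random draws agree with the scalar-loop reference cell to 1e-6
  set.seed(12)
  for (variant in c("printed", "standard")) {
    for (rep in 1:5) {
      x <- rnorm(3); h0 <- rnorm(4); c0 <- rnorm(4)
      a <- lstm_step(p, x, h0, c0, variant)
      b <- ref_lstm_step(p, x, h0, c0, variant)
      expect_equal(a$h, b$h, tolerance = 1e-6)
      expect_equal(a$c, b$c, tolerance = 1e-6)
    }
  }
  expect_true(all(st$gf > 0 & st$gf < 1))
  expect_error(lstm_step(p, rnorm(2), rep(0, 4), rep(0, 4)), "length")
})

test_that("BiLSTM respects the time-reversal / direction-swap symmetry", {
  set.seed(6)
  model <- list(fwd = lstm_init(4, 5, 1), bwd = lstm_init(4, 5, 2),
                W_out = matrix(rnorm(20), 10), b_out = c(0.1, -0.1),
                variant = "printed")
  X <- matrix(rnorm(7 * 4), 7)
  p1 <- bilstm_forward(model, X)
  swapped <- model
  swapped$fwd <- model$bwd; swapped$bwd <- model$fwd
  # softmax head sees [h_fwd, h_bwd]; swap the block order to match
  swapped$W_out <- model$W_out[c(6:10, 1:5), ]
  p2 <- bilstm_forward(swapped, X[7:1, , drop = FALSE])
  expect_equal(p2, p1[7:1, , drop = FALSE], tolerance = 1e-6)
  # single-window sequence is well defined and normalized
  p3 <- bilstm_forward(model, X[1, , drop = FALSE])
  expect_equal(sum(p3), 1, tolerance = 1e-12)
})

test_that("BiLSTM training learns a separable sequence problem", {
  set.seed(8)
  mk <- function(n) {
    lapply(seq_len(n), function(i) {
      y <- rep(sample(0:1, 1), 6)
      X <- cbind(1 - y + rnorm(6, 0, 0.2), y + rnorm(6, 0, 0.2),
                 1 - y + rnorm(6, 0, 0.2), y + rnorm(6, 0, 0.2))
      list(X = X, y = y)
    })
  }
  tr <- mk(24); te <- mk(10)
  m <- fit_bilstm(lapply(tr, `[[`, "X"), lapply(tr, `[[`, "y"),
                  hidden_size = 6, epochs = 25, seed = 2)
  acc <- mean(unlist(lapply(te, function(s)
    predict(m, s$X, type = "class") == s$y)))
  expect_gte(acc, 0.95)
  expect_lt(utils::tail(m$history, 1), utils::head(m$history, 1))
})

test_that("evaluation metrics follow the printed formulas", {
  ev <- evaluate(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_identical(ev$se, 1)
  expect_identical(ev$ppv, 1)
  expect_identical(ev$acc, 1)
  # TP=9, FN=1 -> Se = 0.9
  ev <- evaluate(c(rep(1, 9), 0), rep(1, 10))
  expect_equal(ev$se, 0.9)
  # TP=90, FP=5, FN=5 -> Acc = 0.9 (printed form, no TN)
  pred <- c(rep(1, 95), rep(0, 5))
  lab <- c(rep(1, 90), rep(0, 5), rep(1, 5))
  ev <- evaluate(pred, lab)
  expect_identical(c(ev$tp, ev$fp, ev$fn), c(90L, 5L, 5L))
  expect_equal(ev$acc, 0.9)
  expect_error(evaluate(integer(0), integer(0)), "empty")
  expect_error(evaluate(1, c(1, 0)), "length")

  expect_identical(mean_abs_error(c(1, 2), c(1, 2)), 0)
  expect_equal(mean_abs_error(c(1.0, 1.1), c(0.9, 1.0)), 0.1)
  a <- runif(5); b <- runif(5)
  expect_identical(mean_abs_error(a, b), mean_abs_error(b, a))
  expect_error(mean_abs_error(1:3, 1:4), "length")
})

test_that("model stacks survive a text checkpoint round trip", {
  cfg <- cnn_config(32L, 3L, c(5L), c(6L), dropout = 0)
  set.seed(3)
  x <- matrix(rnorm(20 * 32), 20); y <- rep(0:1, 10)
  hr <- fit_cnn(x, y, cfg, epochs = 2, seed = 1)
  face <- fit_cnn(x, y, cfg, epochs = 2, seed = 2)
  seqs <- list(matrix(rnorm(12), 3), matrix(rnorm(16), 4))
  fus <- fit_bilstm(seqs, list(c(0, 1, 0), c(1, 1, 0, 0)),
                    hidden_size = 3, epochs = 2, seed = 3)
  models <- structure(list(hr = hr, face = face, fusion = fus, seed = 1L),
                      class = "fatigue_models")
  p <- file.path(withr::local_tempdir(), "ckpt.json")
  save_fatigue_models(models, p)
  m2 <- load_fatigue_models(p)
  xt <- matrix(rnorm(3 * 32), 3)
  expect_equal(predict(m2$hr, xt), predict(hr, xt), tolerance = 1e-12)
  expect_equal(predict(m2$fusion, seqs[[1]]), predict(fus, seqs[[1]]),
               tolerance = 1e-12)
})
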