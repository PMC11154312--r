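# LSTM cell and bidirectional fusion head. The cell follows the gate
# equations Gamma_f/u/o = sigmoid(W [h, x] + b), C~ = tanh(W_c [h, x] + b_c),
# C_t = Gamma_u * C~ + Gamma_f * C_{t-1}; the default output equation is the
# printed variant h_t = Gamma_o * C_t (no tanh on the cell state); the
# conventional h_t = Gamma_o * tanh(C_t) is available via variant =
# "standard". Training is plain backprop-through-time with Adam.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize LSTM cell parameters
#'
#' Weight matrices act on the concatenated `[h_prev, x_t]` vector.
#'
#' @param input_size input dimension.
#' @param hidden_size hidden state dimension.
#' @param seed integer seed.
#' @return list with matrices `Wf`, `Wu`, `Wc`, `Wo` (each
#'   `hidden x (hidden + input)`) and bias vectors `bf`, `bu`, `bc`, `bo`.
#'   The forget bias is initialized to 1 (standard practice).
#' @export
lstm_init <- function(input_size, hidden_size, seed = 1L) {
  d <- hidden_size + input_size
  with_seed(seed, {
    mk <- function() matrix(stats::rnorm(hidden_size * d, 0, 1 / sqrt(d)),
                            hidden_size, d)
    list(Wf = mk(), Wu = mk(), Wc = mk(), Wo = mk(),
         bf = rep(1, hidden_size), bu = numeric(hidden_size),
         bc = numeric(hidden_size), bo = numeric(hidden_size),
         hidden_size = hidden_size, input_size = input_size)
  })
}

#' One LSTM time step
#'
#' @param params parameters from [lstm_init()].
#' @param x_t input vector at time t.
#' @param h_prev,c_prev previous hidden and cell state vectors.
#' @param variant `"printed"` uses `h_t = Gamma_o * C_t`; `"standard"` uses
#'   `h_t = Gamma_o * tanh(C_t)`.
#' @return list with `h`, `c` and the gate activations (`gf`, `gu`, `go`,
#'   `cc`), each of length `hidden_size`.
#' @export
lstm_step <- function(params, x_t, h_prev, c_prev,
                      variant = c("printed", "standard")) {
  variant <- match.arg(variant)
  if (length(x_t) != params$input_size)
    stopf("x_t has length %d; cell expects %d", length(x_t), params$input_size)
  if (length(h_prev) != params$hidden_size || length(c_prev) != params$hidden_size)
    stopf("state vectors must have length %d", params$hidden_size)
  z <- c(h_prev, x_t)
  gf <- sigmoid(as.numeric(params$Wf %*% z) + params$bf)
  gu <- sigmoid(as.numeric(params$Wu %*% z) + params$bu)
  cc <- tanh(as.numeric(params$Wc %*% z) + params$bc)
  go <- sigmoid(as.numeric(params$Wo %*% z) + params$bo)
  cst <- gu * cc + gf * c_prev
  h <- if (variant == "printed") go * cst else go * tanh(cst)
  list(h = h, c = cst, gf = gf, gu = gu, go = go, cc = cc)
}

# Forward pass over a sequence X [T x input]; returns H [T x hidden] plus
# caches for BPTT.
lstm_forward <- function(params, X, variant = "printed") {
  Tn <- nrow(X); hs <- params$hidden_size
  H <- matrix(0, Tn, hs); C <- matrix(0, Tn, hs)
  steps <- vector("list", Tn)
  h <- numeric(hs); cs <- numeric(hs)
  for (t in seq_len(Tn)) {
    st <- lstm_step(params, X[t, ], h, cs, variant)
    steps[[t]] <- c(st, list(h_prev = h, c_prev = cs, x = X[t, ]))
    h <- st$h; cs <- st$c
    H[t, ] <- h; C[t, ] <- cs
  }
  list(H = H, C = C, steps = steps)
}

# BPTT through one direction. dH: [T x hidden] gradients w.r.t. outputs.
lstm_backward <- function(params, fw, dH, variant = "printed") {
  hs <- params$hidden_size
  Tn <- nrow(dH)
  g <- list(Wf = params$Wf * 0, Wu = params$Wu * 0, Wc = params$Wc * 0,
            Wo = params$Wo * 0, bf = numeric(hs), bu = numeric(hs),
            bc = numeric(hs), bo = numeric(hs))
  dh_next <- numeric(hs); dc_next <- numeric(hs)
  for (t in rev(seq_len(Tn))) {
    st <- fw$steps[[t]]
    dh <- dH[t, ] + dh_next
    if (variant == "printed") {
      dgo <- dh * st$c
      dc <- dh * st$go + dc_next
    } else {
      tc <- tanh(st$c)
      dgo <- dh * tc
      dc <- dh * st$go * (1 - tc^2) + dc_next
    }
    dgu <- dc * st$cc
    dcc <- dc * st$gu
    dgf <- dc * st$c_prev
    dc_next <- dc * st$gf
    dzf <- dgf * st$gf * (1 - st$gf)
    dzu <- dgu * st$gu * (1 - st$gu)
    dzo <- dgo * st$go * (1 - st$go)
    dzc <- dcc * (1 - st$cc^2)
    z <- c(st$h_prev, st$x)
    g$Wf <- g$Wf + tcrossprod(dzf, z); g$bf <- g$bf + dzf
    g$Wu <- g$Wu + tcrossprod(dzu, z); g$bu <- g$bu + dzu
    g$Wc <- g$Wc + tcrossprod(dzc, z); g$bc <- g$bc + dzc
    g$Wo <- g$Wo + tcrossprod(dzo, z); g$bo <- g$bo + dzo
    dz <- as.numeric(crossprod(params$Wf, dzf) + crossprod(params$Wu, dzu) +
                     crossprod(params$Wc, dzc) + crossprod(params$Wo, dzo))
    dh_next <- dz[seq_len(hs)]
  }
  g
}

#' Bidirectional LSTM forward pass over one sequence
#'
#' Runs one LSTM forward in time and a second one over the reversed
#' sequence, concatenates the two hidden states at each step, and maps them
#' through a softmax head to per-step class probabilities. By construction,
#' reversing the input sequence while swapping the two directions' parameter
#' sets yields the reversed predictions.
#'
#' @param model a `fatigue_bilstm` model (or a bare parameter list with
#'   `fwd`, `bwd`, `W_out`, `b_out`, `variant`).
#' @param X numeric matrix, one time step per row.
#' @return matrix of per-step class probabilities.
#' @export
bilstm_forward <- function(model, X) {
  fw <- lstm_forward(model$fwd, X, model$variant)
  bw <- lstm_forward(model$bwd, X[rev(seq_len(nrow(X))), , drop = FALSE],
                     model$variant)
  Hb <- bw$H[rev(seq_len(nrow(X))), , drop = FALSE]
  Z <- cbind(fw$H, Hb) %*% model$W_out +
    matrix(model$b_out, nrow(X), length(model$b_out), byrow = TRUE)
  softmax_rows(Z)
}

flat_params <- function(p) c("Wf", "Wu", "Wc", "Wo", "bf", "bu", "bc", "bo")

#' Fit the BiLSTM fusion head
#'
#' Trains a bidirectional LSTM that fuses per-window model outputs (the
#' concatenated heart-rate and face class probabilities, or any per-window
#' feature vector) into per-window fatigue probabilities. Sequences are
#' processed one at a time with full backprop-through-time and Adam.
#'
#' @param sequences list of numeric matrices, one per session (rows =
#'   windows).
#' @param labels list of 0/1 label vectors, aligned with `sequences`.
#' @param hidden_size LSTM hidden width per direction (default 8).
#' @param epochs training epochs (default 40).
#' @param lr Adam learning rate (default 0.01).
#' @param variant LSTM output equation, `"printed"` (default) or
#'   `"standard"` (see [lstm_step()]).
#' @param seed integer seed.
#' @param verbose print per-epoch loss.
#' @return object of class `fatigue_bilstm`.
#' @export
fit_bilstm <- function(sequences, labels, hidden_size = 8L, epochs = 40L,
                       lr = 0.01, variant = c("printed", "standard"),
                       seed = 1L, verbose = FALSE) {
  variant <- match.arg(variant)
  if (length(sequences) != length(labels)) stopf("sequences and labels differ in length")
  for (i in seq_along(sequences))
    if (nrow(sequences[[i]]) != length(labels[[i]]))
      stopf("sequence %d has %d windows but %d labels", i,
            nrow(sequences[[i]]), length(labels[[i]]))
  input_size <- ncol(sequences[[1]])
  n_classes <- 2L
  model <- list(
    fwd = lstm_init(input_size, hidden_size, derive_seed(seed, "fwd")),
    bwd = lstm_init(input_size, hidden_size, derive_seed(seed, "bwd")),
    W_out = with_seed(derive_seed(seed, "head"),
                      matrix(stats::rnorm(2 * hidden_size * n_classes, 0,
                                          1 / sqrt(2 * hidden_size)),
                             2 * hidden_size, n_classes)),
    b_out = numeric(n_classes),
    variant = variant)
  zero_dir <- function(p) {
    z <- lapply(p[flat_params(p)], function(m) m * 0)
    z
  }
  adam <- list(t = 0L,
               m = list(fwd = zero_dir(model$fwd), bwd = zero_dir(model$bwd),
                        W_out = model$W_out * 0, b_out = model$b_out * 0),
               v = list(fwd = zero_dir(model$fwd), bwd = zero_dir(model$bwd),
                        W_out = model$W_out * 0, b_out = model$b_out * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step_one <- function(p, gr, m, v, t) {
    m <- b1 * m + (1 - b1) * gr
    v <- b2 * v + (1 - b2) * gr^2
    list(p = p - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps),
         m = m, v = v)
  }
  history <- numeric(0)
  with_seed(derive_seed(seed, "order"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(sequences))
      losses <- numeric(0)
      for (si in ord) {
        X <- sequences[[si]]; y <- as.integer(labels[[si]])
        Tn <- nrow(X)
        fw <- lstm_forward(model$fwd, X, variant)
        bw <- lstm_forward(model$bwd, X[rev(seq_len(Tn)), , drop = FALSE], variant)
        Hb <- bw$H[rev(seq_len(Tn)), , drop = FALSE]
        Hcat <- cbind(fw$H, Hb)
        Z <- Hcat %*% model$W_out +
          matrix(model$b_out, Tn, n_classes, byrow = TRUE)
        probs <- softmax_rows(Z)
        onehot <- diag(n_classes)[y + 1L, , drop = FALSE]
        losses <- c(losses, -mean(log(pmax(rowSums(probs * onehot), 1e-12))))
        dZ <- (probs - onehot) / Tn
        gW_out <- crossprod(Hcat, dZ)
        gb_out <- colSums(dZ)
        dH <- dZ %*% t(model$W_out)
        hs <- hidden_size
        g_f <- lstm_backward(model$fwd, fw, dH[, seq_len(hs), drop = FALSE], variant)
        dHb <- dH[, hs + seq_len(hs), drop = FALSE]
        g_b <- lstm_backward(model$bwd, bw,
                             dHb[rev(seq_len(Tn)), , drop = FALSE], variant)
        adam$t <- adam$t + 1L
        for (nm in flat_params(model$fwd)) {
          r <- step_one(model$fwd[[nm]], g_f[[nm]], adam$m$fwd[[nm]],
                        adam$v$fwd[[nm]], adam$t)
          model$fwd[[nm]] <- r$p; adam$m$fwd[[nm]] <- r$m; adam$v$fwd[[nm]] <- r$v
          r <- step_one(model$bwd[[nm]], g_b[[nm]], adam$m$bwd[[nm]],
                        adam$v$bwd[[nm]], adam$t)
          model$bwd[[nm]] <- r$p; adam$m$bwd[[nm]] <- r$m; adam$v$bwd[[nm]] <- r$v
        }
        r <- step_one(model$W_out, gW_out, adam$m$W_out, adam$v$W_out, adam$t)
        model$W_out <- r$p; adam$m$W_out <- r$m; adam$v$W_out <- r$v
        r <- step_one(model$b_out, gb_out, adam$m$b_out, adam$v$b_out, adam$t)
        model$b_out <- r$p; adam$m$b_out <- r$m; adam$v$b_out <- r$v
      }
      history <- c(history, mean(losses))
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, mean(losses)))
    }
  })
  structure(c(model, list(history = history, hidden_size = hidden_size,
                          seed = as.integer(seed))),
            class = "fatigue_bilstm")
}

#' @export
predict.fatigue_bilstm <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  seqs <- if (is.list(newdata) && !is.data.frame(newdata)) newdata else list(newdata)
  out <- lapply(seqs, function(X) {
    p <- bilstm_forward(object, as.matrix(X))
    if (type == "prob") p else max.col(p) - 1L
  })
  if (length(out) == 1L) out[[1]] else out
}

#' @export
print.fatigue_bilstm <- function(x, ...) {
  cat(sprintf("BiLSTM fusion head: input %d, hidden %d per direction (%s output equation)\n",
              x$fwd$input_size, x$hidden_size, x$variant))
  if (length(x$history))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                length(x$history), x$history[length(x$history)]))
  invisible(x)
}
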