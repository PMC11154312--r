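# One-dimensional convolutional classifiers for the heart-rate and facial
# feature vectors. Both nets share a small valid-convolution architecture
# (three conv layers, two fully connected layers, softmax over two fatigue
# states) and are trained with Adam on softmax cross-entropy. Convolutions
# are evaluated as patch-matrix products (im2col), so all heavy work is
# BLAS matrix multiplication.

#' 1-D CNN architecture configuration
#'
#' @param input_len input vector length.
#' @param n_filters filters per convolutional layer.
#' @param kernels integer vector of kernel lengths, one per conv layer.
#' @param fc_sizes integer vector of fully connected layer widths.
#' @param n_classes output classes (softmax; default 2 fatigue states).
#' @param dropout dropout rate applied after each fully connected layer
#'   during training (default 0.5).
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(input_len, n_filters, kernels, fc_sizes,
                       n_classes = 2L, dropout = 0.5) {
  check_number(input_len, "input_len", lower = 8)
  check_number(n_filters, "n_filters", lower = 1)
  check_number(dropout, "dropout", lower = 0, upper = 0.95)
  len <- input_len
  for (k in kernels) {
    len <- len - k + 1L
    if (len < 1L) stopf("kernel chain exhausts the input (length %d before kernel %d)", len + k - 1L, k)
  }
  structure(list(input_len = as.integer(input_len),
                 n_filters = as.integer(n_filters),
                 kernels = as.integer(kernels),
                 fc_sizes = as.integer(fc_sizes),
                 n_classes = as.integer(n_classes),
                 dropout = dropout,
                 flat_len = as.integer(len * n_filters)),
            class = "cnn_config")
}

#' Heart-rate model architecture
#'
#' Input 1024, three conv layers of 32 filters with kernels 16, 8 and 4,
#' fully connected layers of 256 and 128 units, two-way softmax.
#' @param dropout dropout rate (default 0.5).
#' @return a [cnn_config()].
#' @export
hr_cnn_config <- function(dropout = 0.5)
  cnn_config(1024L, 32L, c(16L, 8L, 4L), c(256L, 128L), dropout = dropout)

#' Face model architecture
#'
#' Input 600, three conv layers of 24 filters with kernels 10, 5 and 3,
#' fully connected layers of 128 and 64 units, two-way softmax.
#' @param dropout dropout rate (default 0.5).
#' @return a [cnn_config()].
#' @export
face_cnn_config <- function(dropout = 0.5)
  cnn_config(600L, 24L, c(10L, 5L, 3L), c(128L, 64L), dropout = dropout)

#' Initialize CNN parameters
#'
#' He-scaled Gaussian weights, zero biases; deterministic for a given seed.
#'
#' @param cfg a [cnn_config()].
#' @param seed integer seed.
#' @return list of weight/bias matrices (`conv` and `fc` layer lists).
#' @export
cnn_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "cnn_config"))
  with_seed(seed, {
    conv <- list()
    ch_in <- 1L
    for (i in seq_along(cfg$kernels)) {
      fan_in <- cfg$kernels[i] * ch_in
      conv[[i]] <- list(
        W = matrix(stats::rnorm(fan_in * cfg$n_filters, 0, sqrt(2 / fan_in)),
                   fan_in, cfg$n_filters),
        b = numeric(cfg$n_filters))
      ch_in <- cfg$n_filters
    }
    fc <- list()
    sizes <- c(cfg$flat_len, cfg$fc_sizes, cfg$n_classes)
    for (i in seq_len(length(sizes) - 1L)) {
      fc[[i]] <- list(
        W = matrix(stats::rnorm(sizes[i] * sizes[i + 1L], 0, sqrt(2 / sizes[i])),
                   sizes[i], sizes[i + 1L]),
        b = numeric(sizes[i + 1L]))
    }
    list(conv = conv, fc = fc)
  })
}

# im2col: A [B, L, C] -> patches [B*Lout, k*C] for kernel length k.
im2col1d <- function(A, k) {
  B <- dim(A)[1]; L <- dim(A)[2]; C <- dim(A)[3]
  Lout <- L - k + 1L
  Xp <- matrix(0, B * Lout, k * C)
  for (c in seq_len(C)) for (kk in seq_len(k))
    Xp[, (c - 1L) * k + kk] <- as.vector(A[, kk:(kk + Lout - 1L), c])
  Xp
}

col2im1d <- function(dXp, B, L, C, k) {
  Lout <- L - k + 1L
  dA <- array(0, c(B, L, C))
  for (c in seq_len(C)) for (kk in seq_len(k))
    dA[, kk:(kk + Lout - 1L), c] <- dA[, kk:(kk + Lout - 1L), c] +
      matrix(dXp[, (c - 1L) * k + kk], B)
  dA
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass over a batch. x: matrix [B, input_len]. Returns probabilities
# and (when cache = TRUE) every intermediate needed for the backward pass.
cnn_forward_pass <- function(cfg, params, x, train = FALSE, cache = FALSE) {
  B <- nrow(x)
  A <- array(x, c(B, cfg$input_len, 1L))
  caches <- list(conv = list(), fc = list())
  for (i in seq_along(params$conv)) {
    k <- cfg$kernels[i]
    Xp <- im2col1d(A, k)
    Z <- sweep(Xp %*% params$conv[[i]]$W, 2, params$conv[[i]]$b, "+")
    R <- pmax(Z, 0)
    if (cache) caches$conv[[i]] <- list(Xp = Xp, Z = Z, dimA = dim(A))
    A <- array(R, c(B, dim(A)[2] - k + 1L, cfg$n_filters))
  }
  H <- matrix(A, B)  # flatten [B, flat_len]
  n_fc <- length(params$fc)
  for (i in seq_len(n_fc)) {
    Z <- sweep(H %*% params$fc[[i]]$W, 2, params$fc[[i]]$b, "+")
    if (i < n_fc) {
      R <- pmax(Z, 0)
      mask <- NULL
      if (train && cfg$dropout > 0) {
        mask <- matrix(stats::rbinom(length(R), 1, 1 - cfg$dropout),
                       nrow(R)) / (1 - cfg$dropout)
        R <- R * mask
      }
      if (cache) caches$fc[[i]] <- list(H = H, Z = Z, mask = mask)
      H <- R
    } else {
      if (cache) caches$fc[[i]] <- list(H = H, Z = Z)
      H <- Z
    }
  }
  probs <- softmax_rows(H)
  if (cache) list(probs = probs, caches = caches) else probs
}

# Backward pass; returns gradients with the same structure as params.
cnn_backward_pass <- function(cfg, params, caches, probs, y_onehot) {
  B <- nrow(probs)
  g <- list(conv = vector("list", length(params$conv)),
            fc = vector("list", length(params$fc)))
  delta <- (probs - y_onehot) / B
  for (i in rev(seq_along(params$fc))) {
    cc <- caches$fc[[i]]
    g$fc[[i]] <- list(W = crossprod(cc$H, delta), b = colSums(delta))
    delta <- delta %*% t(params$fc[[i]]$W)
    if (i > 1L) {
      prev <- caches$fc[[i - 1L]]
      if (!is.null(prev$mask)) delta <- delta * prev$mask
      delta <- delta * (prev$Z > 0)
    }
  }
  # delta now w.r.t. the flattened conv output
  for (i in rev(seq_along(params$conv))) {
    cc <- caches$conv[[i]]
    Lout <- cc$dimA[2] - cfg$kernels[i] + 1L
    dR <- matrix(delta, B * Lout, cfg$n_filters)
    dZ <- dR * (cc$Z > 0)
    g$conv[[i]] <- list(W = crossprod(cc$Xp, dZ), b = colSums(dZ))
    if (i > 1L) {
      dXp <- dZ %*% t(params$conv[[i]]$W)
      dA <- col2im1d(dXp, B, cc$dimA[2], cc$dimA[3], cfg$kernels[i])
      delta <- matrix(dA, B)
    }
  }
  g
}

# In-place-style Adam update over the nested parameter list.
adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, gr, m, v) {
    m <- beta1 * m + (1 - beta1) * gr
    v <- beta2 * v + (1 - beta2) * gr^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (grp in c("conv", "fc")) {
    for (i in seq_along(params[[grp]])) {
      for (nm in c("W", "b")) {
        r <- upd(params[[grp]][[i]][[nm]], grads[[grp]][[i]][[nm]],
                 state$m[[grp]][[i]][[nm]], state$v[[grp]][[i]][[nm]])
        params[[grp]][[i]][[nm]] <- r$p
        state$m[[grp]][[i]][[nm]] <- r$m
        state$v[[grp]][[i]][[nm]] <- r$v
      }
    }
  }
  list(params = params, state = state)
}

zeros_like <- function(params)
  lapply(params, function(grp) lapply(grp, function(layer)
    lapply(layer, function(p) p * 0)))

#' Forward pass through a 1-D CNN
#'
#' Deterministic in evaluation mode (dropout disabled): returns class
#' probabilities that are non-negative and sum to one per sample.
#'
#' @param cfg a [cnn_config()].
#' @param params parameters from [cnn_init()] or a fitted model.
#' @param x numeric vector of length `cfg$input_len`, or a matrix with one
#'   sample per row.
#' @return matrix of class probabilities, one row per sample.
#' @export
forward_cnn <- function(cfg, params, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (ncol(x) != cfg$input_len)
    stopf("input length %d does not match the architecture (%d)",
          ncol(x), cfg$input_len)
  cnn_forward_pass(cfg, params, x, train = FALSE)
}

#' Fit a 1-D CNN fatigue classifier
#'
#' Trains with Adam on softmax cross-entropy, mini-batches of
#' `batch_size`, for at most `epochs` epochs; fully deterministic for a
#' fixed seed.
#'
#' @param x training inputs, one sample per row (`cfg$input_len` columns).
#' @param y binary labels (0 = awake, 1 = fatigued).
#' @param cfg a [cnn_config()] matching `ncol(x)`.
#' @param epochs maximum training epochs (default 30).
#' @param batch_size mini-batch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed integer seed for init, shuffling and dropout.
#' @param standardize standardize columns to zero mean / unit variance using
#'   training statistics (default `TRUE`; the statistics are stored and
#'   re-applied at prediction time).
#' @param verbose print the per-epoch loss.
#' @return object of class `fatigue_cnn` with elements `cfg`, `params`,
#'   `history` (per-epoch mean loss), `center`, `scale`.
#' @export
fit_cnn <- function(x, y, cfg, epochs = 30L, batch_size = 32L, lr = 1e-3,
                    seed = 1L, standardize = TRUE, verbose = FALSE) {
  stopifnot(inherits(cfg, "cnn_config"))
  x <- as.matrix(x)
  if (ncol(x) != cfg$input_len)
    stopf("x has %d columns; architecture expects %d", ncol(x), cfg$input_len)
  y <- as.integer(y)
  if (!all(y %in% 0:(cfg$n_classes - 1L))) stopf("labels must be in 0..%d", cfg$n_classes - 1L)
  center <- scale_ <- NULL
  if (standardize) {
    center <- colMeans(x)
    scale_ <- pmax(apply(x, 2, stats::sd), 1e-8)
    x <- sweep(sweep(x, 2, center), 2, scale_, "/")
  }
  params <- cnn_init(cfg, seed = derive_seed(seed, "init"))
  state <- list(t = 0L, m = zeros_like(params), v = zeros_like(params))
  onehot <- diag(cfg$n_classes)[y + 1L, , drop = FALSE]
  n <- nrow(x)
  history <- numeric(0)
  with_seed(derive_seed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (s in seq(1L, n, by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        fw <- cnn_forward_pass(cfg, params, x[idx, , drop = FALSE],
                               train = TRUE, cache = TRUE)
        yb <- onehot[idx, , drop = FALSE]
        losses <- c(losses, -mean(log(pmax(rowSums(fw$probs * yb), 1e-12))))
        grads <- cnn_backward_pass(cfg, params, fw$caches, fw$probs, yb)
        r <- adam_update(params, grads, state, lr)
        params <- r$params; state <- r$state
      }
      history <- c(history, mean(losses))
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, mean(losses)))
    }
  })
  structure(list(cfg = cfg, params = params, history = history,
                 center = center, scale = scale_, seed = as.integer(seed)),
            class = "fatigue_cnn")
}

#' @export
predict.fatigue_cnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (is.null(dim(newdata))) matrix(newdata, 1) else as.matrix(newdata)
  if (!is.null(object$center))
    x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  p <- forward_cnn(object$cfg, object$params, x)
  if (type == "prob") p else max.col(p) - 1L
}

#' @export
print.fatigue_cnn <- function(x, ...) {
  cat(sprintf("1-D CNN fatigue classifier: input %d, conv %s x %d filters, fc %s\n",
              x$cfg$input_len, paste(x$cfg$kernels, collapse = "/"),
              x$cfg$n_filters, paste(x$cfg$fc_sizes, collapse = "/")))
  if (length(x$history))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                length(x$history), x$history[length(x$history)]))
  invisible(x)
}
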