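# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' = %g outside allowed range [%g, %g]", name, x, lower, upper)
  invisible(x)
}

#' Derive a per-stream seed from a root seed
#'
#' Every stochastic stage derives its own seed from one root seed and a short
#' stream label, so that independent streams stay independent while the whole
#' run remains reproducible from a single integer.
#'
#' @param seed integer root seed.
#' @param stream character label of the random stream.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  check_number(seed, "seed")
  h <- 17
  for (b in utf8ToInt(paste0(stream, ":", format(seed)))) {
    h <- (h * 69069 + b) %% 2147483647  # exact in doubles: product < 2^53
  }
  as.integer(h %% 2147483629 + 1)
}

# Evaluate `expr` under a local RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FNV-1a hash of a serialized R object, as a hex string. Used to stamp
# reports with a configuration fingerprint without extra dependencies.
object_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) {
    h <- (h * 69069 + b) %% 2147483647  # exact in doubles: product < 2^53
  }
  sprintf("%08x", as.integer(h))
}
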