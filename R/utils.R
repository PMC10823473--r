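# Small numeric and RNG utilities shared across modules.

#' Numerically stable log(sum(exp(x)))
#'
#' @param x numeric vector (may contain -Inf).
#' @return scalar log-sum-exp.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(m) {
  rmax <- apply(m, 1L, max)
  ok <- is.finite(rmax)
  out <- rmax
  if (any(ok)) {
    out[ok] <- rmax[ok] + log(rowSums(exp(m[ok, , drop = FALSE] - rmax[ok])))
  }
  out
}

#' Block-jackknife standard error of a (weighted) mean
#'
#' Splits the series into contiguous blocks and estimates the standard error
#' of the overall weighted mean by delete-one-block jackknife.  Blocks
#' longer than the autocorrelation time make this a valid error estimate for
#' correlated trajectory data, and the jackknife handles the ratio form of
#' importance-weighted means (where weight mass can concentrate in a few
#' blocks) that a plain SD of block means mis-estimates.
#'
#' @param x numeric series (trajectory order).
#' @param w optional non-negative weights, same length as `x`.
#' @param n_blocks number of contiguous blocks (default 10).
#' @return estimated standard error of the weighted mean of `x`.
#' @export
block_se <- function(x, w = NULL, n_blocks = 10L) {
  n <- length(x)
  if (n < n_blocks) stop("need at least `n_blocks` observations")
  if (is.null(w)) w <- rep(1, n)
  idx <- ceiling(seq_len(n) / (n / n_blocks))
  sw <- rowsum(w, idx)[, 1L]
  swx <- rowsum(w * x, idx)[, 1L]
  b <- length(sw)
  loo <- (sum(swx) - swx) / (sum(sw) - sw)  # mean with block left out
  loo <- loo[is.finite(loo)]                # guard: a block may carry ~all weight
  if (length(loo) < 2L) return(NA_real_)
  sqrt((b - 1) / b * sum((loo - mean(loo))^2))
}

# --- explicit RNG streams -------------------------------------------------
#
# R has a single global RNG; replicas and the exchange layer each need their
# own reproducible stream so trajectories do not depend on replica count or
# on whether exchanges are attempted.  A stream object stashes a private
# .Random.seed and swaps it in around every draw.

save_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_global_seed <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", s, envir = globalenv())
  }
}

#' Create an explicitly seeded RNG stream
#'
#' @param seed integer seed.
#' @return an object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  old <- save_global_seed()
  on.exit(restore_global_seed(old))
  set.seed(as.integer(seed))
  e <- new.env(parent = emptyenv())
  e$state <- get(".Random.seed", envir = globalenv())
  class(e) <- "rng_stream"
  e
}

#' Evaluate a random-number-drawing function under a stream
#'
#' The global RNG state is swapped for the stream's state, `fn` is called,
#' and the advanced state is written back to the stream.
#'
#' @param stream an `rng_stream`.
#' @param fn zero-argument function performing the draws.
#' @export
stream_draw <- function(stream, fn) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- save_global_seed()
  assign(".Random.seed", stream$state, envir = globalenv())
  out <- fn()
  stream$state <- get(".Random.seed", envir = globalenv())
  restore_global_seed(old)
  out
}

#' Derive reproducible substream seeds from a master seed
#'
#' Used to give each replica (and the exchange layer) its own stream; the
#' first k seeds are identical whatever the total number requested, so a
#' single run and replica 1 of a ladder share a noise sequence.
#'
#' @param seed master integer seed.
#' @param n number of substream seeds.
#' @return integer vector of `n` seeds, each in [1, 2^31 - 2].
#' @export
substream_seeds <- function(seed, n) {
  old <- save_global_seed()
  on.exit(restore_global_seed(old))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# trapezoid integral of y sampled on x (uniform or not)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
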