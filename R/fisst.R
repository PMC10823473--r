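# Infinite-switch simulated tempering in force (FISST).
#
# The bias samples the force-mixture ensemble
#     p(q) propto exp(-beta U(q)) * int dF omega(F) exp(beta F Q(q))
# over a force grid [f_min, f_max].  omega(F) is learned on the fly towards
# omega propto 1/Z_q(F), at which point every force is sampled evenly and a
# single trajectory can be reweighted to any F inside the grid.  All force
# integrals are grid quadratures evaluated in log space (log-sum-exp with a
# max shift) so that large beta*F*Q never overflows.

#' Discretized force grid with quadrature weights
#'
#' Uniform nodes from `f_min` to `f_max` inclusive with trapezoid quadrature
#' weights (weights sum to `f_max - f_min`).  A degenerate grid
#' (`f_min == f_max`, one node) represents a single constant force; its
#' quadrature weight is 1 so a normalized point mass integrates to 1.
#'
#' @param f_min,f_max force range (reduced units; k_B = 1 throughout).
#' @param n_points number of nodes (default 121).
#' @return object of class `force_grid` with fields `f_min`, `f_max`,
#'   `n_points`, `nodes`, `weights`.
#' @export
force_grid <- function(f_min, f_max, n_points = 121L) {
  stopifnot(is.numeric(f_min), is.numeric(f_max), length(f_min) == 1L,
            length(f_max) == 1L, is.finite(f_min), is.finite(f_max))
  if (f_max < f_min) stop("f_max must be >= f_min")
  n_points <- as.integer(n_points)
  if (n_points < 1L) stop("n_points must be >= 1")
  if (f_max == f_min || n_points == 1L) {
    if (f_max != f_min) stop("a single-node grid requires f_min == f_max")
    nodes <- f_min
    w <- 1
  } else {
    nodes <- seq(f_min, f_max, length.out = n_points)
    h <- (f_max - f_min) / (n_points - 1L)
    w <- c(h / 2, rep(h, n_points - 2L), h / 2)
  }
  structure(list(f_min = f_min, f_max = f_max, n_points = length(nodes),
                 nodes = nodes, weights = w),
            class = "force_grid")
}

#' @export
print.force_grid <- function(x, ...) {
  cat(sprintf("<force_grid> [%g, %g], %d nodes (trapezoid quadrature)\n",
              x$f_min, x$f_max, x$n_points))
  invisible(x)
}

#' Adaptive FISST state
#'
#' Holds the force grid, the log force-weight density `log_omega`
#' (normalized so that the grid quadrature of omega is exactly 1), the
#' running log partition-function accumulator, the absorbed sample count and
#' the frozen flag.  The initial omega is uniform.
#'
#' @param grid a [force_grid()].
#' @param beta inverse temperature entering every `exp(beta F Q)` factor
#'   (each replica uses its own beta).
#' @param update_interval number of MD steps between weight updates
#'   (default 500).
#' @return object of class `fisst_state`.
#' @export
fisst_state <- function(grid, beta, update_interval = 500L) {
  stopifnot(inherits(grid, "force_grid"), is.numeric(beta), beta > 0,
            is.finite(beta))
  update_interval <- as.integer(update_interval)
  if (update_interval < 1L) stop("update_interval must be >= 1")
  n <- grid$n_points
  structure(list(
    grid = grid,
    beta = beta,
    log_omega = rep(-log(sum(grid$weights)), n),
    log_zsum = rep(-Inf, n),   # log sum_t e^{beta F Q_t} / m_t(Q_t)
    n_samples = 0L,
    n_updates = 0L,
    frozen = FALSE,
    update_interval = update_interval
  ), class = "fisst_state")
}

#' @export
print.fisst_state <- function(x, ...) {
  cat(sprintf(paste0("<fisst_state> grid [%g, %g] x %d, beta = %g, ",
                     "%d samples, %d updates%s\n"),
              x$grid$f_min, x$grid$f_max, x$grid$n_points, x$beta,
              x$n_samples, x$n_updates, if (x$frozen) ", FROZEN" else ""))
  invisible(x)
}

# per-node log integrand of int dF omega(F) e^{beta F Q}, for scalar Q
tilted_log_weights <- function(state, Q) {
  log(state$grid$weights) + state$log_omega + state$beta * state$grid$nodes * Q
}

#' Log mixture normalizer log int dF omega(F) exp(beta F Q)
#'
#' Vectorized over `Q`.  This is the per-frame denominator of the observable
#' weights and (times -1/beta) the bias potential.
#'
#' @param state a [fisst_state()].
#' @param Q collective-variable value(s).
#' @return numeric vector, same length as `Q`.
#' @export
log_mixture <- function(state, Q) {
  if (any(!is.finite(Q))) stop("Q must be finite")
  base <- log(state$grid$weights) + state$log_omega
  if (length(Q) == 1L) return(logsumexp(base + state$beta * state$grid$nodes * Q))
  m <- outer(Q, state$beta * state$grid$nodes)
  m <- sweep(m, 2L, base, "+")
  row_logsumexp(m)
}

#' On-the-fly applied force F-bar(Q)
#'
#' The omega-weighted, exponentially tilted mean force
#' \deqn{\bar F(Q) = \frac{\int dF\,\omega(F)\,F\,e^{\beta F Q}}
#'                        {\int dF\,\omega(F)\,e^{\beta F Q}}}
#' applied along the collective variable during FISST dynamics.  Always lies
#' in `[f_min, f_max]` (it is a convex combination of the grid nodes) and is
#' non-decreasing in `Q`.
#'
#' @param Q collective-variable value (scalar or vector).
#' @param state a [fisst_state()].
#' @return force value(s).
#' @export
fbar <- function(Q, state) {
  if (any(!is.finite(Q))) stop("Q must be finite")
  nodes <- state$grid$nodes
  if (length(nodes) == 1L) return(rep(nodes, length(Q)))
  vapply(Q, function(qq) {
    lw <- tilted_log_weights(state, qq)
    p <- exp(lw - max(lw))
    sum(p * nodes) / sum(p)
  }, numeric(1))
}

#' FISST bias potential V(Q) = -(1/beta) log int dF omega(F) exp(beta F Q)
#'
#' Its negative derivative with respect to Q equals [fbar()]; the MD force
#' contribution is therefore `fbar(Q) * grad Q`.
#'
#' @inheritParams fbar
#' @return energy value(s).
#' @export
bias_potential <- function(Q, state) {
  -log_mixture(state, Q) / state$beta
}

#' Observable weight W_F(q) for reweighting to a fixed force
#'
#' \deqn{W_F(q) = e^{\beta F Q} / \int dF'\,\omega(F')\,e^{\beta F' Q}}
#' Any Q-independent normalization cancels in reweighted averages and is
#' omitted.  `F` must lie inside the grid range; extrapolation is refused.
#'
#' @param Q collective-variable value(s).
#' @param F target force.
#' @param state a [fisst_state()].
#' @return strictly positive weight(s).
#' @export
observable_weight <- function(Q, F, state) {
  check_force_in_grid(F, state$grid)
  exp(state$beta * F * Q - log_mixture(state, Q))
}

check_force_in_grid <- function(F, grid) {
  if (!is.numeric(F) || any(!is.finite(F))) stop("target force must be finite")
  if (any(F < grid$f_min) || any(F > grid$f_max)) {
    stop(sprintf("target force %g outside grid range [%g, %g]; extrapolation refused",
                 F[which(F < grid$f_min | F > grid$f_max)[1L]],
                 grid$f_min, grid$f_max))
  }
  invisible(TRUE)
}

#' Update the force weights from new CV samples
#'
#' Accumulates the mixture-importance estimator of the configurational
#' partition function,
#' \deqn{\hat z(F) \propto \textstyle\sum_t e^{\beta F Q_t} / m_t(Q_t)}
#' where `m_t` is the mixture normalizer in force at sampling time, then sets
#' `omega proportional to 1/zhat`, renormalized so the grid quadrature of omega is
#' exactly 1.  A frozen state is returned unchanged with a warning.
#'
#' @param state a [fisst_state()].
#' @param Q new CV samples.
#' @param log_mix optional per-sample log mixture normalizers recorded at
#'   sampling time (as during dynamics); computed from the current state if
#'   omitted.
#' @return the updated `fisst_state`.
#' @export
update_weights <- function(state, Q, log_mix = NULL) {
  if (state$frozen) {
    warning("update_weights called on a frozen fisst_state; no-op")
    return(state)
  }
  if (length(Q) < 1L) stop("need at least one sample")
  if (any(!is.finite(Q))) stop("Q samples must be finite")
  if (is.null(log_mix)) log_mix <- log_mixture(state, Q)
  stopifnot(length(log_mix) == length(Q))
  # contribution per node: logsumexp_t (beta F_i Q_t - log_mix_t)
  m <- outer(state$beta * state$grid$nodes, Q)
  m <- sweep(m, 2L, log_mix, "-")
  contrib <- row_logsumexp(m)
  lz <- pmax(state$log_zsum, contrib) +
    log1p(exp(-abs(state$log_zsum - contrib)))
  lz[is.infinite(state$log_zsum) & state$log_zsum < 0] <-
    contrib[is.infinite(state$log_zsum) & state$log_zsum < 0]
  state$log_zsum <- lz
  state$n_samples <- state$n_samples + length(Q)
  # omega propto 1/zhat; the 1/n factor is constant in F and drops out
  log_unnorm <- -state$log_zsum
  log_norm <- logsumexp(log(state$grid$weights) + log_unnorm)
  state$log_omega <- log_unnorm - log_norm
  state$n_updates <- state$n_updates + 1L
  state
}

#' Freeze the force weights
#'
#' After freezing, [update_weights()] is a no-op; [fbar()], [bias_potential()]
#' and [observable_weight()] are unchanged.  Idempotent.
#'
#' @param state a [fisst_state()].
#' @return the frozen state.
#' @export
freeze_weights <- function(state) {
  state$frozen <- TRUE
  state
}

# --- restart file ---------------------------------------------------------
# Self-describing plain text; doubles printed with %.17g so the round trip
# is bit-exact.

RESTART_MAGIC <- "# forcetemper fisst restart"
RESTART_VERSION <- 1L

#' Write a FISST state to a plain-text restart file
#'
#' @param state a [fisst_state()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fisst_restart <- function(state, path) {
  stopifnot(inherits(state, "fisst_state"))
  g <- state$grid
  hdr <- c(
    RESTART_MAGIC,
    sprintf("format_version: %d", RESTART_VERSION),
    sprintf("f_min: %.17g", g$f_min),
    sprintf("f_max: %.17g", g$f_max),
    sprintf("n_points: %d", g$n_points),
    sprintf("beta: %.17g", state$beta),
    sprintf("update_interval: %d", state$update_interval),
    sprintf("n_samples: %d", state$n_samples),
    sprintf("n_updates: %d", state$n_updates),
    sprintf("frozen: %d", as.integer(state$frozen)),
    "# node log_omega log_zsum"
  )
  rows <- sprintf("%.17g %.17g %.17g", g$nodes, state$log_omega, state$log_zsum)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a FISST state from a restart file
#'
#' Fails with an explicit parse error on version mismatch, truncation or
#' corruption; never silently resets.
#'
#' @param path file path written by [write_fisst_restart()].
#' @return a [fisst_state()].
#' @export
read_fisst_restart <- function(path) {
  if (!file.exists(path)) stop("restart file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 12L || lines[1L] != RESTART_MAGIC) {
    stop("not a forcetemper restart file: ", path)
  }
  field <- function(i, key) {
    parts <- strsplit(lines[i], ": ", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || parts[1L] != key) {
      stop(sprintf("restart parse error at line %d: expected key '%s'", i, key))
    }
    parts[2L]
  }
  ver <- as.integer(field(2L, "format_version"))
  if (!identical(ver, RESTART_VERSION)) {
    stop("restart format version mismatch: file has ", ver)
  }
  f_min <- as.numeric(field(3L, "f_min"))
  f_max <- as.numeric(field(4L, "f_max"))
  n_points <- as.integer(field(5L, "n_points"))
  beta <- as.numeric(field(6L, "beta"))
  update_interval <- as.integer(field(7L, "update_interval"))
  n_samples <- as.integer(field(8L, "n_samples"))
  n_updates <- as.integer(field(9L, "n_updates"))
  frozen <- as.integer(field(10L, "frozen")) == 1L
  body <- lines[-(1:11)]
  if (length(body) != n_points) {
    stop(sprintf("restart truncated: expected %d node rows, found %d",
                 n_points, length(body)))
  }
  parse_g <- function(s) {
    # %.17g prints infinities as "inf"/"-inf", which as.numeric rejects
    s <- tolower(s)
    ifelse(s == "-inf", -Inf, ifelse(s == "inf", Inf,
           suppressWarnings(as.numeric(s))))
  }
  mat <- matrix(NA_real_, n_points, 3L)
  for (i in seq_len(n_points)) {
    v <- parse_g(strsplit(body[i], " ", fixed = TRUE)[[1L]])
    if (length(v) != 3L || anyNA(v)) {
      stop(sprintf("restart parse error in node row %d", i))
    }
    mat[i, ] <- v
  }
  state <- fisst_state(force_grid(f_min, f_max, n_points), beta,
                       update_interval)
  if (any(abs(mat[, 1L] - state$grid$nodes) > 0)) {
    stop("restart node positions inconsistent with grid header")
  }
  state$log_omega <- mat[, 2L]
  state$log_zsum <- mat[, 3L]
  state$n_samples <- n_samples
  state$n_updates <- n_updates
  state$frozen <- frozen
  state
}
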