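# Dense-grid quadrature references for 1D (CV-space) fixtures.  These are
# the independent ground truth the sampler is validated against: Boltzmann
# expectations at fixed force, log partition-function ratios, the exact
# FISST mixture density, and exact binned probabilities / PMFs.

#' 1D quadrature oracle
#'
#' Tabulates a potential on a dense CV grid (use >= 10x the resolution of
#' anything being checked).  Expectations converge to better than 1e-6
#' relative under grid doubling for smooth confining potentials.
#'
#' @param potential function U(q), vectorized.
#' @param beta inverse temperature.
#' @param q_min,q_max integration range; the Boltzmann tail mass outside is
#'   checked at evaluation time.
#' @param n number of grid points (default 4001).
#' @return object of class `quadrature_oracle`.
#' @export
quadrature_oracle <- function(potential, beta, q_min, q_max, n = 4001L) {
  stopifnot(is.function(potential), beta > 0, q_max > q_min, n >= 3L)
  q <- seq(q_min, q_max, length.out = as.integer(n))
  structure(list(q = q, U = potential(q), beta = beta,
                 potential = potential),
            class = "quadrature_oracle")
}

# log Boltzmann factor at force F on the grid, with tail check
oracle_log_boltzmann <- function(oracle, F) {
  lw <- -oracle$beta * (oracle$U - F * oracle$q)
  mx <- max(lw)
  dens <- exp(lw - mx)
  ends <- c(dens[1L], dens[length(dens)])
  if (any(ends > 1e-10)) {
    stop(sprintf("Boltzmann tail mass not negligible at the grid edges (%.2g); widen [q_min, q_max]",
                 max(ends)))
  }
  lw
}

#' Boltzmann expectation of an observable at fixed force
#'
#' `int O(Q) e^{-beta(U - F Q)} dQ / int e^{-beta(U - F Q)} dQ` by trapezoid
#' quadrature on the dense grid.
#'
#' @param oracle a [quadrature_oracle()].
#' @param observable function O(q), vectorized.
#' @param F constant force.
#' @return scalar expectation.
#' @export
boltzmann_expectation <- function(oracle, observable, F = 0) {
  lw <- oracle_log_boltzmann(oracle, F)
  w <- exp(lw - max(lw))
  trapz(oracle$q, w * observable(oracle$q)) / trapz(oracle$q, w)
}

#' Log configurational partition-function ratio log Z_q(F) - log Z_q(0)
#'
#' For the harmonic fixture (stiffness k, center mu) this equals
#' `beta F mu + beta F^2 / (2 k)` exactly.
#'
#' @inheritParams boltzmann_expectation
#' @return scalar log ratio.
#' @export
partition_log_ratio <- function(oracle, F) {
  lw_f <- oracle_log_boltzmann(oracle, F)
  lw_0 <- oracle_log_boltzmann(oracle, 0)
  log_int <- function(lw) {
    mx <- max(lw)
    mx + log(trapz(oracle$q, exp(lw - mx)))
  }
  log_int(lw_f) - log_int(lw_0)
}

#' Exact FISST mixture density on the oracle grid
#'
#' The normalized target of a FISST run:
#' `p(Q) proportional to e^{-beta U} int dF omega(F) e^{beta F Q}` with the state's grid
#' quadrature for the force integral.  The state's beta must match the
#' oracle's.
#'
#' @param oracle a [quadrature_oracle()].
#' @param state a [fisst_state()].
#' @return data.frame with columns `q` and `density` (integrates to 1).
#' @export
mixture_density <- function(oracle, state) {
  if (abs(state$beta - oracle$beta) > 1e-12) {
    stop("state beta does not match oracle beta")
  }
  lw <- -oracle$beta * oracle$U + log_mixture(state, oracle$q)
  mx <- max(lw)
  dens <- exp(lw - mx)
  ends <- c(dens[1L], dens[length(dens)])
  if (any(ends > 1e-10)) {
    stop("mixture density tail not negligible at the grid edges; widen the oracle range")
  }
  dens <- dens / trapz(oracle$q, dens)
  data.frame(q = oracle$q, density = dens)
}

#' Fixed-force Boltzmann density on the oracle grid
#'
#' @inheritParams boltzmann_expectation
#' @return data.frame with columns `q` and `density`.
#' @export
fixed_force_density <- function(oracle, F = 0) {
  lw <- oracle_log_boltzmann(oracle, F)
  dens <- exp(lw - max(lw))
  dens <- dens / trapz(oracle$q, dens)
  data.frame(q = oracle$q, density = dens)
}

# integrate a dense density into histogram bins: cumulative trapezoid
# evaluated at the bin edges by interpolation, so partial grid cells at the
# edges are handled exactly (to the density's linear interpolation)
density_bin_probs <- function(q, dens, bin_edges) {
  n <- length(q)
  cw <- c(0, cumsum((q[-1L] - q[-n]) * (dens[-1L] + dens[-n]) / 2))
  edges <- pmin(pmax(bin_edges, q[1L]), q[n])
  ce <- stats::approx(q, cw, xout = edges)$y
  p <- pmax(diff(ce), 0)
  if (sum(p) <= 0) stop("no density mass inside the requested bins")
  p / sum(p)
}

#' Exact binned probabilities at fixed force (oracle reference)
#'
#' Integrates the fixed-force Boltzmann density into the given bins; the
#' direct reference for reweighted histograms.
#'
#' @inheritParams boltzmann_expectation
#' @param bin_edges histogram bin edges.
#' @return probability vector over bins (sums to 1).
#' @export
oracle_bin_probs <- function(oracle, bin_edges, F = 0) {
  d <- fixed_force_density(oracle, F)
  density_bin_probs(d$q, d$density, bin_edges)
}

#' Exact binned free-energy profile at fixed force
#'
#' @inheritParams oracle_bin_probs
#' @return a `reweighted_profile` (exact probabilities, min-offset free
#'   energy).
#' @export
oracle_profile <- function(oracle, bin_edges, F = 0) {
  p <- oracle_bin_probs(oracle, bin_edges, F)
  new_reweighted_profile(bin_edges, p, F, oracle$beta)
}

#' Exact binned probabilities of the FISST mixture ensemble
#'
#' @inheritParams mixture_density
#' @param bin_edges histogram bin edges.
#' @return probability vector over bins.
#' @export
oracle_mixture_bin_probs <- function(oracle, state, bin_edges) {
  d <- mixture_density(oracle, state)
  density_bin_probs(d$q, d$density, bin_edges)
}
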