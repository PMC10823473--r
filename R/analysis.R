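# Trajectory analysis: fixed-force reweighting of recorded observables,
# free-energy profiles A(Q) = -(1/beta) ln P(Q) (min-offset to zero),
# force-extension curves, and the comparison statistics (Jensen-Shannon
# distance, Spearman rank correlation of free energies, RMSE below a
# free-energy cutoff).
#
# Reweighting uses the per-frame observable weights
# W_F = exp(beta F Q - log m(Q)); by default the mixture normalizer m
# recorded at sampling time is used ("sampling"), matching the property that
# observable weights are correct even before omega has converged; the
# alternative recomputes m from the final/frozen weights ("final").

#' Per-frame log observable weights for a target force
#'
#' @param traj a trajectory (from [fisst_run()] etc.).
#' @param F target force; must lie inside the run's force grid.
#' @param weights_from "sampling" (per-frame normalizers stored at run time,
#'   default) or "final" (recompute from the final weights).
#' @return numeric vector of log W_F per frame (unnormalized).
#' @export
log_observable_weights <- function(traj, F,
                                   weights_from = c("sampling", "final")) {
  weights_from <- match.arg(weights_from)
  state <- attr(traj, "fisst")
  if (is.null(state)) stop("trajectory carries no reweighting state")
  check_force_in_grid(F, state$grid)
  if (weights_from == "sampling") {
    state$beta * F * traj$Q - traj$log_mix
  } else {
    state$beta * F * traj$Q - log_mixture(state, traj$Q)
  }
}

frame_weights <- function(traj, F, weights_from = "sampling") {
  lw <- log_observable_weights(traj, F, weights_from)
  exp(lw - max(lw))
}

#' Reweighted average of a recorded observable at a fixed force
#'
#' `sum_t O_t W_F(q_t) / sum_t W_F(q_t)` over the trajectory frames.  With a
#' degenerate single-force grid all weights are equal and this is the plain
#' mean.
#'
#' @inheritParams log_observable_weights
#' @param observable column name in the trajectory (e.g. "Q").
#' @return scalar reweighted average.
#' @export
reweighted_average <- function(traj, observable = "Q", F = 0,
                               weights_from = c("sampling", "final")) {
  if (nrow(traj) == 0L) stop("empty trajectory")
  if (!observable %in% names(traj)) {
    stop("unknown observable: ", observable)
  }
  w <- frame_weights(traj, F, match.arg(weights_from))
  sum(traj[[observable]] * w) / sum(w)
}

#' Reweighted CV histogram and free-energy profile at a fixed force
#'
#' Per-bin sums of observable weights, normalized; the free energy is
#' `-(1/beta) log p` offset so its minimum is zero, with empty bins carrying
#' `NA` (an explicit missing marker) rather than infinite energies.  The
#' Kish effective sample size `(sum W)^2 / sum W^2` is reported.
#'
#' @inheritParams log_observable_weights
#' @param bin_edges monotone bin edges; default 100 uniform bins over the
#'   observed CV range.
#' @param n_bins bin count used when `bin_edges` is NULL.
#' @param observable column to histogram (default the CV "Q").
#' @return object of class `reweighted_profile` with fields `bin_edges`,
#'   `mids`, `probability`, `free_energy`, `target_force`,
#'   `effective_sample_size`, `beta`.
#' @export
reweighted_histogram <- function(traj, F = 0, bin_edges = NULL, n_bins = 100L,
                                 observable = "Q",
                                 weights_from = c("sampling", "final")) {
  if (nrow(traj) == 0L) stop("empty trajectory")
  x <- traj[[observable]]
  if (is.null(bin_edges)) {
    rng <- range(x)
    if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
    bin_edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  w <- frame_weights(traj, F, match.arg(weights_from))
  idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  keep <- idx >= 1L & idx <= length(bin_edges) - 1L
  p <- numeric(length(bin_edges) - 1L)
  if (any(keep)) {
    agg <- rowsum(w[keep], idx[keep])
    p[as.integer(rownames(agg))] <- agg
  }
  tot <- sum(p)
  if (tot <= 0) stop("no frames fall inside the requested bins")
  p <- p / tot
  beta <- attr(traj, "fisst")$beta
  new_reweighted_profile(bin_edges, p, F, beta,
                         ess = sum(w)^2 / sum(w^2))
}

new_reweighted_profile <- function(bin_edges, p, F, beta, ess = NA_real_) {
  fe <- rep(NA_real_, length(p))
  pos <- p > 0
  fe[pos] <- -log(p[pos]) / beta
  fe <- fe - min(fe, na.rm = TRUE)
  structure(list(
    bin_edges = bin_edges,
    mids = (bin_edges[-1L] + bin_edges[-length(bin_edges)]) / 2,
    probability = p,
    free_energy = fe,
    target_force = F,
    effective_sample_size = ess,
    beta = beta
  ), class = "reweighted_profile")
}

#' @export
print.reweighted_profile <- function(x, ...) {
  cat(sprintf("<reweighted_profile> F = %g, %d bins, ESS = %.0f\n",
              x$target_force, length(x$probability),
              x$effective_sample_size))
  invisible(x)
}

#' Force-extension curve from one reweighted run
#'
#' Reweighted mean and standard deviation of the CV at each requested
#' force.  The `spread` column is one third of the standard deviation (the
#' error-bar convention used for force-extension plots); the full `sd` and a
#' 5-block block-averaged standard error of the mean are also reported.
#'
#' @inheritParams log_observable_weights
#' @param forces vector of target forces (all inside the grid).
#' @param observable CV column (default "Q").
#' @return data.frame with columns force, mean, sd, spread, se, ess.
#' @export
force_extension_curve <- function(traj, forces, observable = "Q",
                                  weights_from = c("sampling", "final")) {
  weights_from <- match.arg(weights_from)
  rows <- lapply(forces, function(ff) {
    w <- frame_weights(traj, ff, weights_from)
    x <- traj[[observable]]
    mu <- sum(x * w) / sum(w)
    v <- sum(w * (x - mu)^2) / sum(w)
    data.frame(force = ff, mean = mu, sd = sqrt(v), spread = sqrt(v) / 3,
               se = block_se(x, w), ess = sum(w)^2 / sum(w^2))
  })
  do.call(rbind, rows)
}

#' Jensen-Shannon distance between two binned distributions
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms, so
#' the distance is symmetric and bounded by 1 (attained for disjoint
#' supports).
#'
#' @param p,q probability vectors on the same bins (both sum to 1).
#' @return distance in [0, 1].
#' @export
jensen_shannon_distance <- function(p, q) {
  if (length(p) != length(q)) stop("distributions must share the same bins")
  if (any(p < 0) || any(q < 0)) stop("negative probabilities")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("distributions must be normalized")
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  sqrt(pmax(0, (kl(p, m) + kl(q, m)) / 2))
}

#' Spearman rank correlation between two free-energy profiles
#'
#' Profiles must share bin edges; bins where either free energy is missing
#' are dropped pairwise.  Ties get average ranks (stats::cor convention).
#'
#' @param profile_a,profile_b `reweighted_profile` objects (or lists with
#'   `bin_edges` and `free_energy`).
#' @return correlation in [-1, 1].
#' @export
spearman_free_energy <- function(profile_a, profile_b) {
  check_common_bins(profile_a, profile_b)
  a <- profile_a$free_energy
  b <- profile_b$free_energy
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("fewer than 3 common bins; correlation undefined")
  stats::cor(a[ok], b[ok], method = "spearman")
}

check_common_bins <- function(a, b) {
  if (length(a$bin_edges) != length(b$bin_edges) ||
      any(abs(a$bin_edges - b$bin_edges) > 1e-9)) {
    stop("profiles are not on common bins")
  }
  invisible(TRUE)
}

#' RMSE between free-energy profiles below a cutoff
#'
#' Root-mean-squared error over the bins where the *reference* free energy
#' is below `cutoff`, after each profile is min-offset to zero (so constant
#' shifts do not count).  Bins inside the cutoff region that are missing in
#' either profile are excluded from the RMSE and reported in the
#' `n_missing` attribute (they indicate unsampled states).
#'
#' @param profile_a profile under test.
#' @param profile_ref reference profile (defines the cutoff region).
#' @param cutoff free-energy cutoff (energy units), > 0.
#' @return RMSE (energy units) with attribute `n_missing`.
#' @export
rmse_below_threshold <- function(profile_a, profile_ref, cutoff) {
  stopifnot(cutoff > 0)
  check_common_bins(profile_a, profile_ref)
  a <- profile_a$free_energy - min(profile_a$free_energy, na.rm = TRUE)
  r <- profile_ref$free_energy - min(profile_ref$free_energy, na.rm = TRUE)
  region <- which(!is.na(r) & r < cutoff)
  if (length(region) == 0L) stop("no reference bins below the cutoff")
  ok <- region[!is.na(a[region])]
  n_missing <- length(region) - length(ok)
  if (length(ok) == 0L) stop("profile has no data in the cutoff region")
  out <- sqrt(mean((a[ok] - r[ok])^2))
  attr(out, "n_missing") <- n_missing
  out
}

#' RMSE of the reweighted profile over growing trajectory prefixes
#'
#' Convergence diagnostic: recomputes the reweighted free-energy profile at
#' `F` from the first fraction of the trajectory and scores it against a
#' reference with [rmse_below_threshold()].
#'
#' @inheritParams log_observable_weights
#' @param profile_ref reference profile (defines bins and cutoff region).
#' @param cutoff free-energy cutoff.
#' @param fractions increasing prefix fractions of the trajectory.
#' @return data.frame with columns fraction, n_frames, rmse, n_missing.
#' @export
rmse_convergence <- function(traj, profile_ref, cutoff, F = 0,
                             fractions = seq(0.1, 1, by = 0.1),
                             weights_from = c("sampling", "final")) {
  weights_from <- match.arg(weights_from)
  rows <- lapply(fractions, function(fr) {
    nf <- max(1L, floor(fr * nrow(traj)))
    pr <- reweighted_histogram(traj[seq_len(nf), , drop = FALSE], F,
                               bin_edges = profile_ref$bin_edges,
                               weights_from = weights_from)
    r <- tryCatch(rmse_below_threshold(pr, profile_ref, cutoff),
                  error = function(e) structure(NA_real_, n_missing = NA_integer_))
    data.frame(fraction = fr, n_frames = nf, rmse = as.numeric(r),
               n_missing = attr(r, "n_missing") %||% NA_integer_)
  })
  do.call(rbind, rows)
}

#' Centered moving average (smoothing for convergence curves)
#'
#' @param x numeric vector.
#' @param k odd window size.
#' @return smoothed vector, same length (edges use shrunken windows).
#' @export
smooth_curve <- function(x, k = 3L) {
  n <- length(x)
  half <- k %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)], na.rm = TRUE)
  }, numeric(1))
}

#' Reweighted 2D histogram of two recorded observables
#'
#' W_F-weighted joint histogram, normalized; its marginals equal the
#' corresponding 1D reweighted histograms on the same edges exactly.
#'
#' @inheritParams log_observable_weights
#' @param obs_x,obs_y trajectory column names.
#' @param x_edges,y_edges bin edges (default `n_bins` uniform bins over each
#'   observed range).
#' @param n_bins default bin count per axis when edges are not given.
#' @return list with `x_edges`, `y_edges`, `probability` (matrix, x by y),
#'   `target_force`, `effective_sample_size`.
#' @export
reweighted_2d_histogram <- function(traj, obs_x, obs_y, F = 0,
                                    x_edges = NULL, y_edges = NULL,
                                    n_bins = 50L,
                                    weights_from = c("sampling", "final")) {
  if (nrow(traj) == 0L) stop("empty trajectory")
  for (nm in c(obs_x, obs_y)) {
    if (!nm %in% names(traj)) stop("unknown observable: ", nm)
  }
  x <- traj[[obs_x]]; y <- traj[[obs_y]]
  edges_of <- function(v, e) {
    if (!is.null(e)) return(e)
    rng <- range(v)
    if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
    seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  }
  x_edges <- edges_of(x, x_edges)
  y_edges <- edges_of(y, y_edges)
  w <- frame_weights(traj, F, match.arg(weights_from))
  ix <- findInterval(x, x_edges, rightmost.closed = TRUE)
  iy <- findInterval(y, y_edges, rightmost.closed = TRUE)
  nx <- length(x_edges) - 1L; ny <- length(y_edges) - 1L
  keep <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  pm <- matrix(0, nx, ny)
  if (any(keep)) {
    flat <- (iy[keep] - 1L) * nx + ix[keep]
    agg <- rowsum(w[keep], flat)
    pm[as.integer(rownames(agg))] <- agg
  }
  tot <- sum(pm)
  if (tot <= 0) stop("no frames fall inside the requested bins")
  list(x_edges = x_edges, y_edges = y_edges, probability = pm / tot,
       target_force = F, effective_sample_size = sum(w)^2 / sum(w^2))
}

#' Write a profile or curve as TSV with a header line
#'
#' @param x a `reweighted_profile` or data.frame.
#' @param path output file.
#' @export
write_profile_tsv <- function(x, path) {
  if (inherits(x, "reweighted_profile")) {
    x <- data.frame(bin_lo = x$bin_edges[-length(x$bin_edges)],
                    bin_hi = x$bin_edges[-1L],
                    probability = x$probability,
                    free_energy = x$free_energy)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
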