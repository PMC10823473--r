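# Shared fixtures and small statistical helpers for the suite.
# Expensive runs are computed once and cached for reuse across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

harmonic_sys <- function() make_harmonic_cv_system(1, 0)

harmonic_oracle <- function() {
  quadrature_oracle(function(q) q^2 / 2, beta = 1, -14, 14)
}

# analytic converged force weights for the harmonic fixture:
# omega(F) proportional to exp(-beta F^2 / (2 k)), normalized under the grid quadrature
harmonic_omega_target <- function(grid, beta = 1, k = 1) {
  t <- exp(-beta * grid$nodes^2 / (2 * k))
  t / sum(grid$weights * t)
}

# standard integrator settings for the 1D fixtures (see methods vignette:
# dt from the 1% harmonic-variance budget, light friction for fast CV
# decorrelation)
std_settings <- function(n_steps, seed = 1L, timestep = 0.2, friction = 0.2,
                         beta = 1) {
  integrator_settings(timestep = timestep, beta = beta, friction = friction,
                      n_steps = n_steps, seed = seed)
}

# comparison binning convention: 8 bins covering +/- 3 sd around a center
comparison_edges <- function(center = 0, sd = 1, n_bins = 8L, half_width = 3) {
  seq(center - half_width * sd, center + half_width * sd,
      length.out = n_bins + 1L)
}

# delete-one-block jackknife SE of the variance of a correlated series
var_jack_se <- function(x, n_blocks = 25L) {
  idx <- ceiling(seq_along(x) / (length(x) / n_blocks))
  loo <- vapply(seq_len(n_blocks), function(b) stats::var(x[idx != b]),
                numeric(1))
  sqrt((n_blocks - 1) / n_blocks * sum((loo - mean(loo))^2))
}

# normalized frame weights for a trajectory at force F
norm_weights <- function(traj, F, weights_from = "sampling") {
  lw <- log_observable_weights(traj, F, weights_from)
  exp(lw - max(lw))
}

# the long harmonic FISST run used by several acceptance checks
harmonic_fisst_run_2e5 <- function() {
  cached("harm_fisst_2e5", function() {
    st <- fisst_state(force_grid(-2, 2, 121), beta = 1, update_interval = 500L)
    fisst_run(harmonic_sys(), st, std_settings(2e5L, seed = 1L))
  })
}

# the double-well hybrid (FISST + 4-replica temperature ladder) run
dw_system <- function() make_double_well_system(8)

dw_oracle <- function() {
  quadrature_oracle(function(q) 8 * (q^2 - 1)^2, beta = 1, -2.5, 2.5)
}

dw_settings <- function(seed = 1L) {
  integrator_settings(timestep = 0.01, beta = 1, friction = 0.05,
                      n_steps = 1e5L, seed = seed)
}

dw_hybrid_run <- function() {
  cached("dw_hybrid", function() {
    st <- fisst_state(force_grid(-2, 2, 121), beta = 1, update_interval = 500L)
    lad <- ladder_config(4, t_base = 1, t_top = 6, mode = "temperature_re",
                         exchange_interval = 25L)
    run_ladder(dw_system(), lad, dw_settings(), fisst = st)
  })
}

# solvated bead-spring chain used by the polymer checks (stiff backbone:
# a force of 2 stretches a bond by 20%)
polymer_protocol_system <- function() {
  make_polymer_system(8, bond_k = 10, excluded_volume_eps = 1,
                      n_solvent = 16, seed = 1L)
}
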