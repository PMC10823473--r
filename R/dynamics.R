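# Langevin propagation of a model system under an optional constant-force or
# FISST bias along the collective variable.
#
# Default integrator is the underdamped BAOAB splitting (one force
# evaluation per step); an overdamped Euler-Maruyama scheme is selectable.
# All randomness flows through explicit rng_stream objects so trajectories
# are bitwise reproducible given (settings, seed) and independent of how
# many replicas run alongside.

#' Integrator settings
#'
#' @param timestep time step (reduced time units); must be small against the
#'   fastest oscillation period (the configurational sampling bias of BAOAB
#'   on a harmonic mode of frequency omega is ~ (omega*dt)^2/4, so dt <= 0.2/omega
#'   keeps it under 1%).
#' @param beta inverse temperature of the thermostat (k_B = 1); `Inf` gives
#'   zero-temperature (noiseless) dynamics.
#' @param friction Langevin friction gamma (1/time).
#' @param n_steps default number of steps for runs using these settings.
#' @param seed master integer seed; substreams for replicas and the exchange
#'   layer are derived from it.
#' @param scheme "baoab" (underdamped, default) or "euler" (overdamped
#'   Euler-Maruyama).
#' @return object of class `integrator_settings`.
#' @export
integrator_settings <- function(timestep, beta, friction = 1, n_steps = 0L,
                                seed = 1L, scheme = c("baoab", "euler")) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(timestep), timestep > 0,
            is.numeric(friction), friction > 0,
            is.numeric(beta), beta > 0)
  structure(list(timestep = timestep, beta = beta, friction = friction,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 scheme = scheme),
            class = "integrator_settings")
}

#' One Langevin step (reference implementation)
#'
#' Single documented step of the selected discretization with total force
#' `-grad U + bias_force_on_cv * grad Q`, taking the per-dof standard-normal
#' noise explicitly so the step is a pure function.  The production loop in
#' [fisst_run()] and friends inlines the same arithmetic.
#'
#' @param system a model system.
#' @param q,v current positions and velocities (`v` ignored for "euler").
#' @param bias_force_on_cv scalar force applied along the CV.
#' @param settings an [integrator_settings()].
#' @param noise standard-normal vector, one entry per dof.
#' @return list with updated `q` and `v`.
#' @export
langevin_step <- function(system, q, v, bias_force_on_cv, settings, noise) {
  if (!is.finite(bias_force_on_cv)) stop("bias force must be finite")
  dt <- settings$timestep
  m <- system$masses
  force_at <- function(qq) {
    potential_force(system, qq) + bias_force_on_cv * system$cv_grad(qq)
  }
  if (settings$scheme == "euler") {
    amp <- sqrt(2 * dt / (settings$beta * settings$friction))
    qn <- q + dt * force_at(q) / settings$friction + amp * noise
    return(list(q = qn, v = v))
  }
  c1 <- exp(-settings$friction * dt)
  c2 <- sqrt((1 - c1^2) / (settings$beta * m))
  f <- force_at(q)
  if (any(!is.finite(f))) stop("non-finite force in langevin_step")
  v1 <- v + (dt / 2) * f / m
  q1 <- q + (dt / 2) * v1
  v2 <- c1 * v1 + c2 * noise
  q2 <- q1 + (dt / 2) * v2
  f2 <- force_at(q2)
  if (any(!is.finite(f2))) stop("non-finite force in langevin_step")
  list(q = q2, v = v2 + (dt / 2) * f2 / m)
}

# --- internal simulation object ------------------------------------------
# A mutable environment so a ladder can propagate replicas in segments.

new_sim <- function(system, settings, stream, bias = NULL, scaling = NULL,
                    record_every = 1L, observables = list(),
                    defer_updates = FALSE) {
  sim <- new.env(parent = emptyenv())
  sim$sys <- system
  sim$dt <- settings$timestep
  sim$gamma <- settings$friction
  sim$beta <- settings$beta
  sim$scheme <- settings$scheme
  sim$m <- system$masses
  sim$scaling <- scaling
  sim$stream <- stream
  sim$record_every <- as.integer(record_every)
  sim$observables <- observables
  sim$defer_updates <- defer_updates
  if (inherits(bias, "fisst_state")) {
    sim$bias_kind <- "fisst"
    sim$fisst <- bias
    sim$bias_F <- NA_real_
    sim$log_qw <- log(bias$grid$weights)        # constant per run
    sim$bnodes <- bias$beta * bias$grid$nodes   # constant per run
  } else {
    sim$bias_kind <- "const"
    sim$bias_F <- if (is.null(bias)) 0 else as.numeric(bias)
    if (!is.finite(sim$bias_F)) stop("constant bias force must be finite")
    sim$fisst <- NULL
  }
  sim$q <- system$positions
  sim$v <- if (is.finite(settings$beta)) {
    stream_draw(stream, function() stats::rnorm(system$ndof)) /
      sqrt(settings$beta * system$masses)
  } else {
    numeric(system$ndof)
  }
  sim$step <- 0L
  sim$pending_Q <- numeric(0)   # FISST samples not yet absorbed
  sim$pending_lm <- numeric(0)
  sim$n_bias_evals <- 0L
  sim$records <- list()
  # BAOAB coefficients
  sim$c1 <- exp(-sim$gamma * sim$dt)
  sim$c2 <- sqrt((1 - sim$c1^2) / (settings$beta * system$masses))
  if (!is.finite(settings$beta)) sim$c2 <- numeric(system$ndof) * 0
  sim$euler_amp <- if (is.finite(settings$beta)) {
    sqrt(2 * sim$dt / (settings$beta * sim$gamma))
  } else 0
  # cache force at the initial configuration
  fe <- sim_eval(sim, sim$q)
  sim$f <- fe$f
  sim$Q <- fe$Q
  sim$lm <- fe$lm
  sim
}

# force + CV + bias bookkeeping at coordinates q
sim_eval <- function(sim, q) {
  Q <- sim$sys$cv(q)
  if (sim$bias_kind == "fisst") {
    st <- sim$fisst
    lwv <- sim$log_qw + st$log_omega + sim$bnodes * Q
    mx <- max(lwv)
    p <- exp(lwv - mx)
    s <- sum(p)
    lm <- mx + log(s)
    fb <- if (st$grid$n_points == 1L) st$grid$nodes else sum(p * st$grid$nodes) / s
  } else {
    fb <- sim$bias_F
    bbeta <- if (is.finite(sim$beta)) sim$beta else 1
    lm <- bbeta * fb * Q
  }
  sim$n_bias_evals <- sim$n_bias_evals + 1L
  f <- potential_force(sim$sys, q, sim$scaling) + fb * sim$sys$cv_grad(q)
  list(f = f, Q = Q, lm = lm, fb = fb)
}

# absorb one post-step CV sample into the FISST machinery
sim_push_sample <- function(sim) {
  if (sim$bias_kind != "fisst") return(invisible())
  sim$pending_Q[length(sim$pending_Q) + 1L] <- sim$Q
  sim$pending_lm[length(sim$pending_lm) + 1L] <- sim$lm
  if (!sim$defer_updates &&
      length(sim$pending_Q) >= sim$fisst$update_interval) {
    if (!sim$fisst$frozen) {
      sim$fisst <- update_weights(sim$fisst, sim$pending_Q, sim$pending_lm)
    }
    sim$pending_Q <- numeric(0)
    sim$pending_lm <- numeric(0)
  }
  invisible()
}

# hand pending samples to a pooled estimator (clears the buffer)
sim_drain_samples <- function(sim) {
  out <- list(Q = sim$pending_Q, lm = sim$pending_lm)
  sim$pending_Q <- numeric(0)
  sim$pending_lm <- numeric(0)
  out
}

sim_propagate <- function(sim, n_steps) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) return(invisible(sim))
  ndof <- sim$sys$ndof
  chunk <- max(1L, 131072L %/% ndof)
  rec_every <- sim$record_every
  n_rec <- sum(((sim$step + seq_len(n_steps)) %% rec_every) == 0L)
  obs_names <- names(sim$observables)
  rec <- list(step = integer(n_rec), Q = numeric(n_rec), U = numeric(n_rec),
              bias = numeric(n_rec), log_mix = numeric(n_rec))
  for (nm in obs_names) rec[[nm]] <- numeric(n_rec)
  ri <- 0L
  done <- 0L
  dt <- sim$dt
  half <- dt / 2
  m <- sim$m
  use_baoab <- sim$scheme == "baoab"
  while (done < n_steps) {
    nb <- min(chunk, n_steps - done)
    noise <- matrix(stream_draw(sim$stream, function() stats::rnorm(nb * ndof)),
                    ndof, nb)
    for (s in seq_len(nb)) {
      if (use_baoab) {
        v1 <- sim$v + half * sim$f / m
        q1 <- sim$q + half * v1
        v2 <- sim$c1 * v1 + sim$c2 * noise[, s]
        q2 <- q1 + half * v2
        fe <- sim_eval(sim, q2)
        sim$q <- q2
        sim$v <- v2 + half * fe$f / m
      } else {
        q2 <- sim$q + dt * sim$f / sim$gamma + sim$euler_amp * noise[, s]
        fe <- sim_eval(sim, q2)
        sim$q <- q2
      }
      sim$step <- sim$step + 1L
      if (any(!is.finite(fe$f))) {
        stop(sprintf("non-finite force/energy at step %d; reduce the timestep",
                     sim$step))
      }
      sim$f <- fe$f
      sim$Q <- fe$Q
      sim$lm <- fe$lm
      sim_push_sample(sim)
      if (sim$step %% rec_every == 0L) {
        ri <- ri + 1L
        rec$step[ri] <- sim$step
        rec$Q[ri] <- fe$Q
        rec$U[ri] <- potential_energy(sim$sys, sim$q, sim$scaling)
        rec$bias[ri] <- if (sim$bias_kind == "fisst") {
          -fe$lm / sim$fisst$beta
        } else {
          -sim$bias_F * fe$Q
        }
        rec$log_mix[ri] <- fe$lm
        for (nm in obs_names) {
          rec[[nm]][ri] <- sim$observables[[nm]](sim$sys, sim$q)
        }
      }
    }
    done <- done + nb
  }
  sim$records[[length(sim$records) + 1L]] <- rec
  invisible(sim)
}

# reweighting state describing the run: the final FISST state, or a
# degenerate single-force state for constant-force/plain runs
sim_reweight_state <- function(sim) {
  if (sim$bias_kind == "fisst") return(sim$fisst)
  bbeta <- if (is.finite(sim$beta)) sim$beta else 1
  fisst_state(force_grid(sim$bias_F, sim$bias_F, 1L), bbeta)
}

sim_trajectory <- function(sim) {
  recs <- sim$records
  cols <- names(recs[[1L]])
  df <- as.data.frame(lapply(stats::setNames(cols, cols), function(cn) {
    unlist(lapply(recs, `[[`, cn), use.names = FALSE)
  }))
  df$time <- df$step * sim$dt
  df <- df[, c("step", "time", setdiff(cols, "step"))]
  attr(df, "fisst") <- sim_reweight_state(sim)
  attr(df, "beta") <- sim$beta
  attr(df, "system_kind") <- sim$sys$kind
  attr(df, "record_every") <- sim$record_every
  attr(df, "timestep") <- sim$dt
  class(df) <- c("ft_trajectory", "data.frame")
  df
}

#' Final FISST (or degenerate single-force) state of a run
#'
#' @param traj a trajectory returned by [fisst_run()], [constant_force_run()]
#'   or [run_ladder()].
#' @return a [fisst_state()].
#' @export
final_fisst_state <- function(traj) attr(traj, "fisst")

# --- user-facing runners --------------------------------------------------

run_single <- function(system, settings, bias, record_every, observables,
                       freeze_after = NULL) {
  seeds <- substream_seeds(settings$seed, 2L)
  stream <- rng_stream(seeds[1L])
  sim <- new_sim(system, settings, stream, bias = bias,
                 record_every = record_every, observables = observables)
  n <- settings$n_steps
  if (!is.null(freeze_after) && inherits(bias, "fisst_state") &&
      freeze_after < n) {
    sim_propagate(sim, freeze_after)
    sim$fisst <- freeze_weights(sim$fisst)
    sim_propagate(sim, n - freeze_after)
  } else {
    sim_propagate(sim, n)
  }
  traj <- sim_trajectory(sim)
  attr(traj, "n_bias_evals") <- sim$n_bias_evals
  traj
}

#' Unbiased Langevin run
#'
#' @param system a model system.
#' @param settings an [integrator_settings()] (with `n_steps` set).
#' @param record_every record every this many steps.
#' @param observables named list of functions `function(system, q)` recorded
#'   per frame alongside the CV.
#' @return a trajectory `data.frame` (class `ft_trajectory`) with columns
#'   step, time, Q, U, bias, log_mix and one column per observable.
#' @export
plain_run <- function(system, settings, record_every = 1L,
                      observables = list()) {
  run_single(system, settings, NULL, record_every, observables)
}

#' Langevin run under a constant pulling force
#'
#' Samples from `exp(-beta (U - F Q))`; identical machinery (and noise
#' sequence) to [fisst_run()] with a degenerate single-force grid.
#'
#' @inheritParams plain_run
#' @param F constant force along the CV.
#' @return a trajectory (see [plain_run()]).
#' @export
constant_force_run <- function(system, F, settings, record_every = 1L,
                               observables = list()) {
  if (!is.numeric(F) || !is.finite(F)) stop("F must be finite")
  run_single(system, settings, F, record_every, observables)
}

#' FISST run: adaptive force-tempered Langevin sampling
#'
#' Propagates the system under the on-the-fly force [fbar()] while learning
#' the force weights omega(F) every `update_interval` steps of the state.  Every
#' MD step contributes exactly one CV sample to the weight estimator.
#'
#' @inheritParams plain_run
#' @param state a [fisst_state()]; its `beta` should match `settings$beta`.
#' @param freeze_after optionally freeze the weights after this many steps
#'   (adaptive equilibration phase, then fixed-weight production).
#' @return a trajectory; the final state is available via
#'   [final_fisst_state()].
#' @export
fisst_run <- function(system, state, settings, record_every = 1L,
                      observables = list(), freeze_after = NULL) {
  stopifnot(inherits(state, "fisst_state"))
  run_single(system, settings, state, record_every, observables,
             freeze_after = freeze_after)
}
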