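# Ladders of replicas -- temperature replica exchange (TRE), REST-style
# solute tempering, or plain parallel runs -- each optionally carrying its
# own FISST bias, with Metropolis neighbor swaps on a deterministic
# alternating even/odd schedule.
#
# FISST statistics are accumulated exactly once per MD step during
# propagation; the swap-evaluation energy calls below are pure functions of
# the states and never touch the weight estimators.

#' Replica-ladder configuration
#'
#' Target temperatures follow the geometric ladder
#' `T_i = t_base * (t_top/t_base)^(i/(N-1))`, i = 0..N-1.  In
#' `temperature_re` mode replica i runs at `beta_i = 1/T_i`; in
#' `rest_scaling` mode every replica runs at `1/t_base` but scales its
#' solute-solute and solute-solvent interactions to emulate a heated solute;
#' `none` runs the replicas in parallel without exchanges.
#'
#' @param n_replicas number of replicas.
#' @param t_base bottom (target) temperature, energy units (k_B = 1).
#' @param t_top top temperature (>= t_base).
#' @param mode one of "temperature_re", "rest_scaling", "none".
#' @param exchange_interval steps between swap attempts.
#' @param kappa REST3 kappa factor(s) for the solute-solvent scaling; a
#'   scalar or one value per replica (see [rest_kappa()]).
#' @return object of class `ladder_config`.
#' @export
ladder_config <- function(n_replicas, t_base, t_top = t_base,
                          mode = c("temperature_re", "rest_scaling", "none"),
                          exchange_interval = 500L, kappa = 1) {
  mode <- match.arg(mode)
  n_replicas <- as.integer(n_replicas)
  if (n_replicas < 1L) stop("n_replicas must be >= 1")
  if (t_top < t_base) stop("t_top must be >= t_base")
  if (t_base <= 0) stop("temperatures must be positive")
  kappa <- rep_len(kappa, n_replicas)
  structure(list(n_replicas = n_replicas, t_base = t_base, t_top = t_top,
                 mode = mode, exchange_interval = as.integer(exchange_interval),
                 kappa = kappa),
            class = "ladder_config")
}

#' Geometric temperature ladder of a configuration
#' @param ladder a [ladder_config()].
#' @return vector of replica target temperatures.
#' @export
ladder_temperatures <- function(ladder) {
  n <- ladder$n_replicas
  if (n == 1L) return(ladder$t_base)
  ladder$t_base * (ladder$t_top / ladder$t_base)^((seq_len(n) - 1L) / (n - 1L))
}

#' Hamiltonian scaling factors of one replica
#'
#' @param lambda_pp solute-solute scale (REST: `T0/Ti`).
#' @param lambda_pw solute-solvent scale (REST2 convention: `sqrt(T0/Ti)`).
#' @param kappa REST3 correction applied to the (non-electrostatic)
#'   solute-solvent term; the toy systems have a single non-bonded class, so
#'   kappa multiplies the whole pw term.
#' @return object of class `replica_scaling`.
#' @export
replica_scaling <- function(lambda_pp = 1, lambda_pw = 1, kappa = 1) {
  stopifnot(is.numeric(lambda_pp), is.numeric(lambda_pw), is.numeric(kappa))
  structure(list(lambda_pp = lambda_pp, lambda_pw = lambda_pw, kappa = kappa),
            class = "replica_scaling")
}

#' REST solute-solute scaling lambda_pp = T0 / Ti
#' @param t0 base temperature.
#' @param ti replica target temperature.
#' @export
rest_lambda_pp <- function(t0, ti) t0 / ti

#' REST solute-solvent scaling (REST2 convention sqrt(T0/Ti))
#' @inheritParams rest_lambda_pp
#' @export
rest_lambda_pw <- function(t0, ti) sqrt(t0 / ti)

#' REST3 kappa factor, kappa = 1 + 0.005 (m - 3) for m > 3, else 1
#' @param m REST3 size parameter (user-supplied).
#' @export
rest_kappa <- function(m) ifelse(m > 3, 1 + 0.005 * (m - 3), 1)

# scaling for replica i of a ladder
scaling_for_replica <- function(ladder, i) {
  temps <- ladder_temperatures(ladder)
  if (ladder$mode == "rest_scaling") {
    replica_scaling(lambda_pp = rest_lambda_pp(ladder$t_base, temps[i]),
                    lambda_pw = rest_lambda_pw(ladder$t_base, temps[i]),
                    kappa = ladder$kappa[i])
  } else {
    replica_scaling()
  }
}

#' Lightweight replica object
#'
#' Bundles a model system, an inverse temperature, Hamiltonian scaling and
#' (optionally) a FISST state with a configuration, for use with
#' [replica_energy()] and [exchange_attempt()].
#'
#' @param system a model system.
#' @param beta inverse temperature of the replica.
#' @param scaling a [replica_scaling()].
#' @param fisst optional [fisst_state()] owned by this replica.
#' @param q configuration (defaults to the system's positions).
#' @param step propagation step count.
#' @return object of class `replica`.
#' @export
replica <- function(system, beta, scaling = replica_scaling(), fisst = NULL,
                    q = system$positions, step = 0L) {
  structure(list(system = system, beta = beta, scaling = scaling,
                 fisst = fisst, q = q, step = as.integer(step)),
            class = "replica")
}

#' Replica Hamiltonian H_i(q): scaled potential plus own FISST bias
#'
#' `H_i = lambda_pp U_pp + kappa lambda_pw U_pw + U_ww + V_i(Q(q))` where
#' `V_i` is the replica's own bias potential (its own omega and beta).  This
#' is the quantity entering the Metropolis exchange criterion.
#'
#' @param rep a [replica()].
#' @param q configuration at which to evaluate (defaults to the replica's).
#' @return scalar energy.
#' @export
replica_energy <- function(rep, q = rep$q) {
  u <- potential_energy(rep$system, q, rep$scaling)
  if (!is.null(rep$fisst)) {
    u <- u + bias_potential(rep$system$cv(q), rep$fisst)
  }
  u
}

#' Metropolis swap attempt between two replicas
#'
#' Computes `Delta = beta_i [H_i(q_j) - H_i(q_i)] + beta_j [H_j(q_i) - H_j(q_j)]`
#' with each Hamiltonian including that replica's own FISST bias, and
#' accepts with probability `min(1, exp(-Delta))`.
#'
#' @param rep_i,rep_j [replica()] objects propagated to the same step count.
#' @param u uniform(0,1) variate deciding acceptance; drawn from `stream`
#'   if omitted.
#' @param stream optional [rng_stream()] owned by the exchange layer.
#' @return list with `delta`, `accepted`, and the four energies.
#' @export
exchange_attempt <- function(rep_i, rep_j, u = NULL, stream = NULL) {
  if (!identical(rep_i$step, rep_j$step)) {
    stop(sprintf("replicas out of sync: steps %d vs %d", rep_i$step, rep_j$step))
  }
  hii <- replica_energy(rep_i, rep_i$q)
  hij <- replica_energy(rep_i, rep_j$q)
  hji <- replica_energy(rep_j, rep_i$q)
  hjj <- replica_energy(rep_j, rep_j$q)
  delta <- rep_i$beta * (hij - hii) + rep_j$beta * (hji - hjj)
  if (is.null(u)) {
    u <- if (!is.null(stream)) {
      stream_draw(stream, function() stats::runif(1))
    } else {
      stats::runif(1)
    }
  }
  accepted <- delta <= 0 || u < exp(-delta)
  list(delta = delta, accepted = accepted,
       h_ii = hii, h_ij = hij, h_ji = hji, h_jj = hjj)
}

#' Merge per-replica FISST statistics into a pooled state
#'
#' Adds the partition-function accumulators of several states sharing the
#' same grid and beta, renormalizing omega from the pooled estimate; with a
#' single state this is the identity.
#'
#' @param states list of [fisst_state()] objects.
#' @return one pooled `fisst_state`.
#' @export
pool_statistics <- function(states) {
  stopifnot(length(states) >= 1L)
  ref <- states[[1L]]
  for (s in states[-1L]) {
    if (!isTRUE(all.equal(s$grid$nodes, ref$grid$nodes)) ||
        s$beta != ref$beta) {
      stop("pooling requires identical force grids and beta across replicas")
    }
  }
  if (length(states) == 1L) return(ref)
  lzs <- vapply(states, `[[`, numeric(ref$grid$n_points), "log_zsum")
  pooled <- ref
  pooled$log_zsum <- row_logsumexp(lzs)
  pooled$n_samples <- sum(vapply(states, `[[`, integer(1), "n_samples"))
  pooled$n_updates <- max(vapply(states, `[[`, integer(1), "n_updates"))
  if (any(is.finite(pooled$log_zsum))) {
    log_unnorm <- -pooled$log_zsum
    pooled$log_omega <- log_unnorm -
      logsumexp(log(pooled$grid$weights) + log_unnorm)
  }
  pooled
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

#' Run a replica ladder with optional FISST on every replica
#'
#' Propagates all replicas with Langevin dynamics, attempting neighbor swaps
#' on the alternating even/odd pair schedule every `exchange_interval`
#' steps.  Each replica owns an independent RNG stream derived from
#' `settings$seed` (replica 1's stream equals the one a single run with the
#' same seed would use); the exchange layer owns a further stream, so
#' trajectories are reproducible and a 1-replica ladder is bitwise identical
#' to the corresponding single run.
#'
#' FISST statistics are accumulated once per MD step; swap-evaluation energy
#' calls contribute no samples.  In pooled mode (`pool = TRUE`, requires a
#' common beta, i.e. rest_scaling or none) all replicas feed one shared
#' weight estimator.
#'
#' @param system a model system (all replicas start from its positions).
#' @param ladder a [ladder_config()].
#' @param settings an [integrator_settings()]; the thermostat beta of each
#'   replica is derived from the ladder (`settings$beta` is ignored), and
#'   `settings$n_steps` is the per-replica length.
#' @param fisst optional [fisst_state()] template; each replica gets a copy
#'   with its own thermostat beta in all `exp(beta F Q)` factors.
#' @param record_every,observables as in [plain_run()].
#' @param pool pool weight statistics across replicas (default per-replica).
#' @return object of class `ladder_run`: list with `trajectories` (one per
#'   replica, bottom first), `exchange_log` data.frame
#'   (attempt, step, i, j, delta, accepted), `acceptance_rate`, `states`
#'   (final per-replica FISST states), `temperatures`, `scalings`,
#'   `walker_trace` (replica x segment matrix of walker identities) and
#'   instrumentation counters.
#' @export
run_ladder <- function(system, ladder, settings, fisst = NULL,
                       record_every = 1L, observables = list(),
                       pool = FALSE) {
  n <- ladder$n_replicas
  temps <- ladder_temperatures(ladder)
  betas <- if (ladder$mode == "temperature_re") 1 / temps else
    rep(1 / ladder$t_base, n)
  if (pool && ladder$mode == "temperature_re") {
    stop("pooled statistics require a common beta (rest_scaling or none mode)")
  }
  seeds <- substream_seeds(settings$seed, n + 1L)
  ex_stream <- rng_stream(seeds[n + 1L])
  sims <- vector("list", n)
  for (i in seq_len(n)) {
    set_i <- settings
    set_i$beta <- betas[i]
    st_i <- NULL
    if (!is.null(fisst)) {
      st_i <- fisst
      st_i$beta <- betas[i]
    }
    sims[[i]] <- new_sim(system, set_i, rng_stream(seeds[i]),
                         bias = st_i, scaling = scaling_for_replica(ladder, i),
                         record_every = record_every,
                         observables = observables,
                         defer_updates = pool && !is.null(fisst))
  }
  shared <- if (pool && !is.null(fisst)) {
    s <- fisst
    s$beta <- betas[1L]
    s
  } else NULL

  n_steps <- settings$n_steps
  seg <- ladder$exchange_interval
  if (!is.null(shared)) seg <- gcd2(seg, shared$update_interval)
  seg <- min(seg, n_steps)
  walkers <- seq_len(n)
  walker_trace <- matrix(NA_integer_, n, 0L)
  log_rows <- list()
  attempt_round <- 0L
  n_attempts <- 0L
  n_accepts <- 0L
  n_ex_energy_evals <- 0L
  done <- 0L

  while (done < n_steps) {
    nb <- min(seg, n_steps - done)
    for (i in seq_len(n)) sim_propagate(sims[[i]], nb)
    done <- done + nb
    if (!is.null(shared)) {
      drained <- lapply(sims, sim_drain_samples)
      qs <- unlist(lapply(drained, `[[`, "Q"))
      lms <- unlist(lapply(drained, `[[`, "lm"))
      if (length(qs) > 0L && !shared$frozen) {
        shared <- update_weights(shared, qs, lms)
      }
      for (i in seq_len(n)) {
        st <- shared
        st$beta <- sims[[i]]$fisst$beta
        sims[[i]]$fisst <- st
      }
    }
    if (ladder$mode != "none" && n >= 2L &&
        done %% ladder$exchange_interval == 0L && done < n_steps + 1L) {
      attempt_round <- attempt_round + 1L
      start <- if (attempt_round %% 2L == 1L) 1L else 2L
      pairs <- if (start <= n - 1L) seq(start, n - 1L, by = 2L) else integer(0)
      for (p in pairs) {
        i <- p; j <- p + 1L
        ri <- replica(system, sims[[i]]$beta,
                      sims[[i]]$scaling %||% replica_scaling(),
                      sims[[i]]$fisst, sims[[i]]$q, sims[[i]]$step)
        rj <- replica(system, sims[[j]]$beta,
                      sims[[j]]$scaling %||% replica_scaling(),
                      sims[[j]]$fisst, sims[[j]]$q, sims[[j]]$step)
        res <- exchange_attempt(ri, rj, stream = ex_stream)
        n_ex_energy_evals <- n_ex_energy_evals + 4L
        n_attempts <- n_attempts + 1L
        if (res$accepted) {
          n_accepts <- n_accepts + 1L
          scale_ij <- sqrt(sims[[i]]$beta / sims[[j]]$beta)
          qi <- sims[[i]]$q; vi <- sims[[i]]$v
          sims[[i]]$q <- sims[[j]]$q
          sims[[i]]$v <- sims[[j]]$v * (1 / scale_ij)  # sqrt(T_i/T_j)... see below
          sims[[j]]$q <- qi
          sims[[j]]$v <- vi * scale_ij
          # refresh cached force/CV under each replica's own Hamiltonian
          for (kk in c(i, j)) {
            fe <- sim_eval(sims[[kk]], sims[[kk]]$q)
            sims[[kk]]$f <- fe$f
            sims[[kk]]$Q <- fe$Q
            sims[[kk]]$lm <- fe$lm
          }
          walkers[c(i, j)] <- walkers[c(j, i)]
        }
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(attempt = n_attempts, step = done, i = i, j = j,
                     delta = res$delta, accepted = res$accepted)
      }
      walker_trace <- cbind(walker_trace, walkers)
    }
  }

  states <- lapply(sims, function(s) {
    if (s$bias_kind == "fisst") s$fisst else NULL
  })
  structure(list(
    trajectories = lapply(sims, sim_trajectory),
    exchange_log = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(attempt = integer(), step = integer(), i = integer(),
                 j = integer(), delta = numeric(), accepted = logical()),
    acceptance_rate = if (n_attempts > 0L) n_accepts / n_attempts else NA_real_,
    states = states,
    temperatures = temps,
    betas = betas,
    scalings = lapply(seq_len(n), function(i) scaling_for_replica(ladder, i)),
    walker_trace = walker_trace,
    n_exchange_energy_evals = n_ex_energy_evals,
    n_samples = vapply(sims, function(s) {
      if (s$bias_kind == "fisst") s$fisst$n_samples else 0L
    }, integer(1)),
    n_steps = n_steps
  ), class = "ladder_run")
}

#' @export
print.ladder_run <- function(x, ...) {
  cat(sprintf("<ladder_run> %d replicas x %d steps, acceptance %.1f%%\n",
              length(x$trajectories), x$n_steps,
              100 * (x$acceptance_rate %||% NA_real_)))
  invisible(x)
}

#' Bottom-replica trajectory of a ladder run
#'
#' All physical results are read from the ladder member at the target
#' (lowest) temperature / unscaled Hamiltonian.
#'
#' @param run a [run_ladder()] result.
#' @export
bottom_replica <- function(run) run$trajectories[[1L]]
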