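# Toy model systems: each system carries positions, masses, solute/solvent
# group labels, potential-energy terms tagged by the particle groups they
# couple (pp = solute-solute, pw = solute-solvent, ww = solvent-solvent),
# and a collective variable with its gradient.  Reduced units throughout:
# k_B = 1, temperature in energy units, lengths dimensionless.
#
# A system is a list with closure fields:
#   energy_terms(q) -> c(pp=, pw=, ww=)
#   grad_terms(q)   -> list(pp=, pw=, ww=)   (gradients of each tagged part)
#   cv(q)           -> scalar Q
#   cv_grad(q)      -> dQ/dq vector

new_model_system <- function(kind, positions, masses, group_labels,
                             energy_terms, grad_terms, cv, cv_grad,
                             cv_kind, box = NULL, params = list()) {
  structure(list(
    kind = kind, positions = positions, masses = masses,
    group_labels = group_labels, energy_terms = energy_terms,
    grad_terms = grad_terms, cv = cv, cv_grad = cv_grad,
    cv_kind = cv_kind, box = box, params = params,
    ndof = length(positions)
  ), class = "model_system")
}

#' @export
print.model_system <- function(x, ...) {
  cat(sprintf("<model_system:%s> %d dof, CV = %s%s\n", x$kind, x$ndof,
              x$cv_kind,
              if (!is.null(x$box)) sprintf(", periodic box L = %g", x$box) else ""))
  invisible(x)
}

#' Total potential energy, optionally with REST-style group scaling
#'
#' U_i = lambda_pp * U_pp + kappa * lambda_pw * U_pw + U_ww.  With all
#' scalings 1 this is exactly the unscaled potential.
#'
#' @param system a model system.
#' @param q coordinate vector (defaults to the stored positions).
#' @param scaling optional [replica_scaling()] (lambda_pp, lambda_pw, kappa).
#' @return scalar energy.
#' @export
potential_energy <- function(system, q = system$positions, scaling = NULL) {
  e <- system$energy_terms(q)
  if (is.null(scaling)) return(sum(e))
  scaling$lambda_pp * e[["pp"]] +
    scaling$kappa * scaling$lambda_pw * e[["pw"]] + e[["ww"]]
}

#' Per-group potential energy components
#'
#' @inheritParams potential_energy
#' @return named vector `c(pp=, pw=, ww=)`.
#' @export
energy_components <- function(system, q = system$positions) {
  system$energy_terms(q)
}

# force = -grad of the (optionally scaled) potential
potential_force <- function(system, q, scaling = NULL) {
  g <- system$grad_terms(q)
  if (is.null(scaling)) return(-(g$pp + g$pw + g$ww))
  -(scaling$lambda_pp * g$pp + scaling$kappa * scaling$lambda_pw * g$pw + g$ww)
}

#' Evaluate the collective variable
#' @inheritParams potential_energy
#' @export
cv_value <- function(system, q = system$positions) system$cv(q)

#' Finite-difference check of potential and CV gradients
#'
#' Compares analytic gradients against central finite differences at random
#' configurations near the stored positions.
#'
#' @param system a model system.
#' @param n_configs number of random configurations.
#' @param seed RNG seed for the configurations.
#' @param h finite-difference step.
#' @return max relative error over configurations, components and both
#'   gradients (potential and CV).
#' @export
check_gradients <- function(system, n_configs = 100L, seed = 1L, h = 1e-5) {
  stream <- rng_stream(seed)
  worst <- 0
  for (i in seq_len(n_configs)) {
    q <- system$positions +
      stream_draw(stream, function() stats::rnorm(system$ndof, sd = 0.3))
    ga <- -potential_force(system, q)
    gc <- system$cv_grad(q)
    scaleU <- max(abs(ga), 1)
    scaleQ <- max(abs(gc), 1)
    for (j in seq_len(system$ndof)) {
      qp <- q; qm <- q
      qp[j] <- q[j] + h; qm[j] <- q[j] - h
      fdU <- (potential_energy(system, qp) - potential_energy(system, qm)) / (2 * h)
      fdQ <- (system$cv(qp) - system$cv(qm)) / (2 * h)
      worst <- max(worst, abs(fdU - ga[j]) / scaleU, abs(fdQ - gc[j]) / scaleQ)
    }
  }
  worst
}

#' Single-coordinate harmonic system U = k (Q - mu)^2 / 2
#'
#' The analytically solvable fixture: under a constant pulling force F the
#' Boltzmann mean is mu + F/k, the variance 1/(beta k), and
#' log Z_q(F) - log Z_q(0) = beta F mu + beta F^2 / (2 k).  The CV is the
#' signed coordinate itself.
#'
#' @param stiffness spring constant k > 0 (energy / length^2).
#' @param center well center mu (length).
#' @return a `model_system`.
#' @export
make_harmonic_cv_system <- function(stiffness = 1, center = 0) {
  if (!is.numeric(stiffness) || length(stiffness) != 1L || stiffness <= 0) {
    stop("stiffness must be a positive scalar")
  }
  k <- stiffness; mu <- center
  new_model_system(
    kind = "harmonic",
    positions = mu, masses = 1, group_labels = "solute",
    energy_terms = function(q) c(pp = k * (q - mu)^2 / 2, pw = 0, ww = 0),
    grad_terms = function(q) list(pp = k * (q - mu), pw = 0, ww = 0),
    cv = function(q) q[1L],
    cv_grad = function(q) 1,
    cv_kind = "signed_coordinate",
    params = list(stiffness = k, center = mu)
  )
}

#' Symmetric quartic double well U = b (Q^2 - 1)^2
#'
#' Minima at Q = +/-1 with U = 0, barrier of height exactly `b` at Q = 0;
#' symmetric under Q -> -Q.  Signed-coordinate CV.
#'
#' @param barrier barrier height b > 0 (energy).
#' @param well_separation distance between the two minima (default 2, i.e.
#'   minima at +/- well_separation/2).
#' @return a `model_system`.
#' @export
make_double_well_system <- function(barrier, well_separation = 2) {
  if (!is.numeric(barrier) || length(barrier) != 1L || barrier <= 0) {
    stop("barrier must be a positive scalar")
  }
  b <- barrier
  a <- well_separation / 2
  u <- function(q) b * ((q / a)^2 - 1)^2
  du <- function(q) b * 4 * (q / a) * ((q / a)^2 - 1) / a
  new_model_system(
    kind = "double_well",
    positions = -a, masses = 1, group_labels = "solute",
    energy_terms = function(q) c(pp = u(q), pw = 0, ww = 0),
    grad_terms = function(q) list(pp = du(q), pw = 0, ww = 0),
    cv = function(q) q[1L],
    cv_grad = function(q) 1,
    cv_kind = "signed_coordinate",
    params = list(barrier = b, well_separation = well_separation)
  )
}

# WCA (purely repulsive Lennard-Jones) energy/force on squared distances
wca_pair <- function(r2, eps, sigma2) {
  rc2 <- sigma2 * 2^(1 / 3)
  act <- r2 < rc2
  e <- numeric(length(r2))
  fog <- numeric(length(r2))  # force magnitude over distance: F/r
  if (any(act)) {
    sr6 <- (sigma2 / r2[act])^3
    e[act] <- 4 * eps * (sr6^2 - sr6) + eps
    fog[act] <- 24 * eps * (2 * sr6^2 - sr6) / r2[act]
  }
  list(e = e, f_over_r = fog)
}

#' 3D bead-spring polymer with optional repulsive solvent
#'
#' A chain of `n_beads` solute beads joined by harmonic bonds (stiffness
#' `bond_k`, rest length `rest_length`), optional WCA excluded volume among
#' non-bonded solute pairs, plus `n_solvent` free solvent particles that
#' repel the solute (pw) and each other (ww) through WCA interactions, in a
#' periodic cubic box (minimum-image convention for pair terms; coordinates
#' kept unwrapped so the CV is a real-space distance).  The CV is the
#' end-to-end distance between the first and last beads.
#'
#' With `n_solvent = 0` and `excluded_volume_eps = 0` this is the ideal
#' chain: bonds are independent and the end-to-end statistics factorize.
#'
#' @param n_beads number of solute beads (>= 2).
#' @param bond_k harmonic bond stiffness.
#' @param excluded_volume_eps WCA epsilon among non-bonded solute pairs
#'   (0 disables).
#' @param n_solvent number of solvent particles.
#' @param solvent_eps WCA epsilon for pw and ww interactions.
#' @param sigma WCA diameter.
#' @param rest_length bond rest length.
#' @param box cubic box edge; defaults to a dilute choice covering the
#'   stretched chain.
#' @param seed seed for the initial solvent placement.
#' @return a `model_system`.
#' @export
make_polymer_system <- function(n_beads, bond_k = 1, excluded_volume_eps = 0,
                                n_solvent = 0, solvent_eps = 1, sigma = 1,
                                rest_length = 1, box = NULL, seed = 1L) {
  n_beads <- as.integer(n_beads)
  if (n_beads < 2L) stop("n_beads must be >= 2")
  n_solvent <- as.integer(n_solvent)
  n <- n_beads + n_solvent
  if (is.null(box)) {
    box <- max(2.5 * (n_beads - 1L) * rest_length, (n / 0.1)^(1 / 3), 5)
  }
  L <- box
  sigma2 <- sigma^2

  # initial coordinates: chain along x through the box center, solvent
  # placed randomly without overlaps
  coords <- matrix(0, 3L, n)
  coords[1L, seq_len(n_beads)] <-
    (seq_len(n_beads) - (n_beads + 1) / 2) * rest_length
  if (n_solvent > 0L) {
    stream <- rng_stream(seed)
    placed <- 0L
    tries <- 0L
    while (placed < n_solvent) {
      tries <- tries + 1L
      if (tries > 10000L * n_solvent) stop("could not place solvent without overlap; enlarge box")
      p <- stream_draw(stream, function() stats::runif(3, -L / 2, L / 2))
      prev <- coords[, seq_len(n_beads + placed), drop = FALSE]
      d <- prev - p
      d <- d - L * round(d / L)
      if (min(colSums(d^2)) > (0.95 * sigma)^2) {
        placed <- placed + 1L
        coords[, n_beads + placed] <- p
      }
    }
  }

  # precomputed pair lists by tag
  bond_i <- seq_len(n_beads - 1L)
  bond_j <- bond_i + 1L
  pairs_for <- function(set_a, set_b) {
    if (identical(set_a, set_b)) {
      if (length(set_a) < 2L) return(NULL)
      cm <- utils::combn(set_a, 2L)
      list(i = cm[1L, ], j = cm[2L, ])
    } else {
      g <- expand.grid(i = set_a, j = set_b)
      list(i = g$i, j = g$j)
    }
  }
  sol <- seq_len(n_beads)
  wat <- if (n_solvent > 0L) n_beads + seq_len(n_solvent) else integer(0)
  pp_nb <- if (excluded_volume_eps > 0 && n_beads > 2L) {
    p <- pairs_for(sol, sol)
    keep <- abs(p$i - p$j) > 1L  # bonded neighbors excluded
    list(i = p$i[keep], j = p$j[keep])
  } else NULL
  pw_pairs <- if (n_solvent > 0L) pairs_for(sol, wat) else NULL
  ww_pairs <- if (n_solvent > 1L) pairs_for(wat, wat) else NULL

  minimg <- function(d) d - L * round(d / L)

  pair_eval <- function(cm, pr, eps) {
    d <- minimg(cm[, pr$i, drop = FALSE] - cm[, pr$j, drop = FALSE])
    r2 <- colSums(d^2)
    w <- wca_pair(r2, eps, sigma2)
    list(d = d, w = w, i = pr$i, j = pr$j)
  }
  pair_force <- function(pe, n) {
    fv <- pe$d * rep(pe$w$f_over_r, each = 3L)
    acc <- rowsum(rbind(t(fv), -t(fv)), c(pe$i, pe$j))
    f <- matrix(0, 3L, n)
    f[, as.integer(rownames(acc))] <- t(acc)
    f
  }

  energy_terms <- function(q) {
    cm <- matrix(q, 3L, n)
    db <- minimg(cm[, bond_j, drop = FALSE] - cm[, bond_i, drop = FALSE])
    r <- sqrt(colSums(db^2))
    e_pp <- sum(bond_k * (r - rest_length)^2 / 2)
    if (!is.null(pp_nb)) {
      e_pp <- e_pp + sum(pair_eval(cm, pp_nb, excluded_volume_eps)$w$e)
    }
    e_pw <- if (!is.null(pw_pairs)) sum(pair_eval(cm, pw_pairs, solvent_eps)$w$e) else 0
    e_ww <- if (!is.null(ww_pairs)) sum(pair_eval(cm, ww_pairs, solvent_eps)$w$e) else 0
    c(pp = e_pp, pw = e_pw, ww = e_ww)
  }

  grad_terms <- function(q) {
    cm <- matrix(q, 3L, n)
    # bonds (pp): force on j along -(r - r0) * unit
    db <- minimg(cm[, bond_j, drop = FALSE] - cm[, bond_i, drop = FALSE])
    r <- sqrt(colSums(db^2))
    r[r < 1e-12] <- 1e-12
    fmag <- -bond_k * (r - rest_length) / r  # F/r on bead j
    fv <- db * rep(fmag, each = 3L)
    f_pp <- matrix(0, 3L, n)
    for (b in seq_along(bond_i)) {
      f_pp[, bond_j[b]] <- f_pp[, bond_j[b]] + fv[, b]
      f_pp[, bond_i[b]] <- f_pp[, bond_i[b]] - fv[, b]
    }
    if (!is.null(pp_nb)) {
      f_pp <- f_pp + pair_force(pair_eval(cm, pp_nb, excluded_volume_eps), n)
    }
    f_pw <- if (!is.null(pw_pairs)) pair_force(pair_eval(cm, pw_pairs, solvent_eps), n) else matrix(0, 3L, n)
    f_ww <- if (!is.null(ww_pairs)) pair_force(pair_eval(cm, ww_pairs, solvent_eps), n) else matrix(0, 3L, n)
    list(pp = -as.vector(f_pp), pw = -as.vector(f_pw), ww = -as.vector(f_ww))
  }

  iend <- (n_beads - 1L) * 3L + 1:3
  cv <- function(q) {
    d <- q[iend] - q[1:3]
    sqrt(sum(d^2))
  }
  cv_grad <- function(q) {
    d <- q[iend] - q[1:3]
    r <- sqrt(sum(d^2))
    g <- numeric(3L * n)
    if (r < 1e-12) return(g)
    g[iend] <- d / r
    g[1:3] <- -d / r
    g
  }

  new_model_system(
    kind = "polymer",
    positions = as.vector(coords),
    masses = rep(1, 3L * n),
    group_labels = c(rep("solute", n_beads), rep("solvent", n_solvent)),
    energy_terms = energy_terms, grad_terms = grad_terms,
    cv = cv, cv_grad = cv_grad,
    cv_kind = "end_end_distance", box = L,
    params = list(n_beads = n_beads, bond_k = bond_k,
                  excluded_volume_eps = excluded_volume_eps,
                  n_solvent = n_solvent, solvent_eps = solvent_eps,
                  sigma = sigma, rest_length = rest_length)
  )
}

#' Write coordinates in XYZ format
#'
#' Solute beads are written as element "C", solvent as "O".
#'
#' @param system a model system (3D coordinates).
#' @param path output file.
#' @param q coordinates to write (defaults to stored positions).
#' @export
write_xyz <- function(system, path, q = system$positions) {
  if (system$ndof %% 3L != 0L) stop("XYZ output requires 3D coordinates")
  n <- system$ndof / 3L
  cm <- matrix(q, 3L, n)
  el <- ifelse(system$group_labels == "solute", "C", "O")
  lines <- c(sprintf("%d", n), sprintf("forcetemper %s", system$kind),
             sprintf("%s %.8f %.8f %.8f", el, cm[1L, ], cm[2L, ], cm[3L, ]))
  writeLines(lines, path)
  invisible(path)
}

#' Read coordinates from an XYZ file
#'
#' @param path XYZ file.
#' @return numeric coordinate vector (xyz interleaved per particle).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(lines[1L])
  if (is.na(n) || length(lines) < n + 2L) stop("malformed XYZ file")
  parts <- strsplit(trimws(lines[2L + seq_len(n)]), "\\s+")
  as.vector(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
}
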