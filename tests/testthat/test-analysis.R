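test_that("Jensen-Shannon distance has the right fixed points", {
  expect_equal(jensen_shannon_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jensen_shannon_distance(c(1, 0), c(0, 1)), 1)  # disjoint, base 2
  # hand evaluation for p = (1, 0), q = (1/2, 1/2)
  kl_p <- log2(1 / 0.75)
  kl_q <- 0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25)
  expect_equal(jensen_shannon_distance(c(1, 0), c(0.5, 0.5)),
               sqrt((kl_p + kl_q) / 2))
  expect_true(abs(jensen_shannon_distance(c(1, 0), c(0.5, 0.5)) - 0.5579227) < 1e-5)
  expect_error(jensen_shannon_distance(c(1, 0), c(0.2, 0.3, 0.5)), "same bins")
  expect_error(jensen_shannon_distance(c(0.9, 0.2), c(0.5, 0.5)), "normalized")
  expect_error(jensen_shannon_distance(c(1.2, -0.2), c(0.5, 0.5)), "negative")
})

test_that("Spearman free-energy correlation is a rank statistic", {
  edges <- 0:10
  p <- exp(-(1:10 - 4)^2 / 6)
  prof <- function(fe) list(bin_edges = edges, free_energy = fe)
  a <- prof(-log(p / sum(p)))
  expect_equal(spearman_free_energy(a, a), 1)
  expect_equal(spearman_free_energy(a, prof(exp(a$free_energy))), 1)
  expect_equal(spearman_free_energy(a, prof(-a$free_energy)), -1)
  # missing bins are dropped pairwise
  b <- a
  b$free_energy[3] <- NA
  expect_equal(spearman_free_energy(a, b), 1)
  few <- prof(c(1, 2, rep(NA, 8)))
  expect_error(spearman_free_energy(a, few), "fewer than 3")
  bad <- list(bin_edges = 0:9, free_energy = a$free_energy[-1])
  expect_error(spearman_free_energy(a, bad), "common bins")
})

test_that("free-energy RMSE below a cutoff is offset-invariant", {
  edges <- 0:3
  prof <- function(fe) list(bin_edges = edges, free_energy = fe)
  a <- prof(c(0, 1, 2))
  expect_equal(as.numeric(rmse_below_threshold(a, a, 6)), 0)
  expect_equal(as.numeric(rmse_below_threshold(prof(c(5, 6, 7)), a, 6)), 0)
  r <- rmse_below_threshold(prof(c(0, 1.3, 2.4)), a, 6)
  expect_equal(as.numeric(r), sqrt((0 + 0.09 + 0.16) / 3))
  expect_identical(attr(r, "n_missing"), 0L)
  # only reference bins below the cutoff enter
  b <- prof(c(0, 1.3, 2.4))
  expect_equal(as.numeric(rmse_below_threshold(b, a, 2)), sqrt(0.09 / 2))
  # an empty reference region is an explicit error
  suppressWarnings(
    expect_error(rmse_below_threshold(a, prof(c(NA, NA, NA)), 6), "below the cutoff")
  )
  expect_error(rmse_below_threshold(a, a, -1))
  # bins missing in the test profile are excluded and counted
  c_ <- prof(c(0, NA, 2.4))
  r2 <- rmse_below_threshold(c_, a, 6)
  expect_identical(attr(r2, "n_missing"), 1L)
  expect_equal(as.numeric(r2), sqrt((0 + 0.16) / 2))
})

test_that("reweighted histograms reduce to plain histograms and track the oracle", {
  trc <- cached("harm_const_hist", function() {
    constant_force_run(harmonic_sys(), 1, std_settings(3e4L, seed = 23L))
  })
  edges <- comparison_edges(1, 1)
  pr <- reweighted_histogram(trc, 1, bin_edges = edges)
  h <- hist(trc$Q, breaks = c(-Inf, edges, Inf), plot = FALSE)$counts
  inside <- h[2:(length(h) - 1L)]
  expect_equal(pr$probability, inside / sum(inside))
  expect_equal(pr$effective_sample_size, nrow(trc))
  expect_equal(sum(pr$probability), 1)
  expect_equal(min(pr$free_energy, na.rm = TRUE), 0)
  orc <- harmonic_oracle()
  expect_lt(jensen_shannon_distance(pr$probability,
                                    oracle_bin_probs(orc, edges, 1)), 0.05)
  # all frames in one bin
  tr1 <- trc[1, , drop = FALSE]
  attr(tr1, "fisst") <- attr(trc, "fisst")
  pr1 <- reweighted_histogram(tr1, 1, bin_edges = c(-100, 100))
  expect_equal(pr1$probability, 1)
  expect_error(reweighted_histogram(trc[0, ], 1), "empty")
  expect_error(reweighted_histogram(trc, 1, bin_edges = c(1, 0)), "increasing")
})

test_that("the harmonic force-extension curve is the line F/k", {
  tr <- cached("harm_fisst_5e4", function() {
    st <- fisst_state(force_grid(-2, 2, 121), beta = 1)
    fisst_run(harmonic_sys(), st, std_settings(5e4L, seed = 12L))
  })
  fec <- force_extension_curve(tr, c(-1, 0, 1))
  expect_named(fec, c("force", "mean", "sd", "spread", "se", "ess"))
  for (i in 1:3) {
    expect_lt(abs(fec$mean[i] - fec$force[i]), 3 * fec$se[i])
  }
  expect_equal(fec$spread, fec$sd / 3)   # reported error-bar convention
  expect_true(all(diff(fec$mean) > 0))
})

test_that("2D reweighted histograms marginalize to the 1D results", {
  s <- make_polymer_system(4, bond_k = 10)
  obs <- list(
    bx1 = function(sys, q) q[4] - q[1],
    bx2 = function(sys, q) q[7] - q[4]
  )
  tr <- cached("poly_2d", function() {
    set <- integrator_settings(timestep = 0.02, beta = 1, friction = 0.5,
                               n_steps = 2e4L, seed = 24L)
    st <- fisst_state(force_grid(-1, 1, 21), beta = 1)
    fisst_run(s, st, set, observables = obs)
  })
  xe <- seq(-2, 2, length.out = 11)
  ye <- seq(-2, 2, length.out = 9)
  h2 <- reweighted_2d_histogram(tr, "bx1", "bx2", F = 0.5,
                                x_edges = xe, y_edges = ye)
  h1x <- reweighted_histogram(tr, 0.5, bin_edges = xe, observable = "bx1")
  h1y <- reweighted_histogram(tr, 0.5, bin_edges = ye, observable = "bx2")
  expect_equal(rowSums(h2$probability), h1x$probability, tolerance = 1e-12)
  expect_equal(colSums(h2$probability), h1y$probability, tolerance = 1e-12)
  # independent bond vectors on the ideal chain: joint ~ product of marginals
  prod_p <- outer(h1x$probability, h1y$probability)
  expect_lt(max(abs(h2$probability - prod_p)), 0.02)
  # a constant observable collapses onto one row
  tr$const <- 1
  h2c <- reweighted_2d_histogram(tr, "bx1", "const", F = 0,
                                 x_edges = xe, y_edges = c(0.5, 1.5))
  expect_equal(as.vector(h2c$probability),
               reweighted_histogram(tr, 0, bin_edges = xe,
                                    observable = "bx1")$probability)
  expect_error(reweighted_2d_histogram(tr, "bx1", "nope", 0), "unknown")
})

test_that("convergence curves and smoothing behave on simple input", {
  expect_equal(smooth_curve(c(1, 2, 3, 4), k = 1), c(1, 2, 3, 4))
  expect_equal(smooth_curve(c(0, 3, 0), k = 3), c(1.5, 1, 1.5))
  tr <- cached("harm_const_hist", function() {
    constant_force_run(harmonic_sys(), 1, std_settings(3e4L, seed = 23L))
  })
  edges <- comparison_edges(1, 1)
  ref <- oracle_profile(harmonic_oracle(), edges, 1)
  conv <- rmse_convergence(tr, ref, cutoff = 8, F = 1,
                           fractions = c(0.25, 0.5, 1))
  expect_equal(conv$n_frames, c(7500L, 15000L, 30000L))
  expect_true(all(is.finite(conv$rmse)))
  expect_lt(conv$rmse[3], 0.25)
})

test_that("profiles serialize to TSV", {
  tr <- cached("harm_const_hist", function() {
    constant_force_run(harmonic_sys(), 1, std_settings(3e4L, seed = 23L))
  })
  pr <- reweighted_histogram(tr, 1, n_bins = 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(pr, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$probability, pr$probability)
  expect_equal(nrow(back), 20)
})
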