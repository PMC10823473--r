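test_that("force grid nodes are uniform and quadrature weights sum to the range", {
  g <- force_grid(-10, 20, 121)
  expect_length(g$nodes, 121)
  expect_equal(diff(g$nodes), rep(0.25, 120))
  expect_equal(sum(g$weights), 30)
  expect_true(all(g$weights > 0))
  # degenerate single-force grid: point mass with unit weight
  g1 <- force_grid(5, 5, 1)
  expect_identical(g1$nodes, 5)
  expect_identical(g1$weights, 1)
  expect_error(force_grid(0, 1, 1), "single-node")
  expect_error(force_grid(2, 1), "f_max")
})

test_that("fbar reduces to the single force and vanishes by symmetry", {
  st1 <- fisst_state(force_grid(5, 5, 1), beta = 1)
  expect_identical(fbar(c(-3, 0, 7.2), st1), rep(5, 3))
  st2 <- fisst_state(force_grid(-3, 3, 61), beta = 1)
  expect_lt(abs(fbar(0, st2)), 1e-12)
})

test_that("fbar matches a 10x-resolution quadrature oracle", {
  # uniform omega on [-10, 20], beta = 1, Q = 0.3; reference evaluated
  # independently on a 1201-node grid (uniform omega cancels in the ratio)
  st <- fisst_state(force_grid(-10, 20, 121), beta = 1)
  nodes <- seq(-10, 20, length.out = 1201)
  h <- diff(nodes[1:2])
  w <- c(h / 2, rep(h, 1199), h / 2)
  lw <- log(w) + 0.3 * nodes
  p <- exp(lw - max(lw))
  ref <- sum(p * nodes) / sum(p)
  expect_lt(abs(fbar(0.3, st) - ref) / abs(ref), 1e-3)
})

test_that("fbar stays inside the grid and is non-decreasing in Q", {
  stream <- rng_stream(21L)
  qs <- seq(-30, 30, length.out = 401)
  for (i in 1:20) {
    st <- fisst_state(force_grid(-2, 2, 41), beta = 1)
    st$log_omega <- stream_draw(stream, function() rnorm(41))
    st$log_omega <- st$log_omega -
      logsumexp(log(st$grid$weights) + st$log_omega)
    fb <- fbar(qs, st)
    expect_true(all(fb >= -2 - 1e-9 & fb <= 2 + 1e-9))
    expect_true(all(diff(fb) >= -1e-10))
  }
})

test_that("bias potential is consistent with fbar and the single-force limit", {
  st1 <- fisst_state(force_grid(3, 3, 1), beta = 2)
  qs <- c(-1.3, 0, 0.7, 2.2)
  v <- bias_potential(qs, st1)
  expect_equal(diff(v), -3 * diff(qs))  # V = -F0 Q + const
  st <- fisst_state(force_grid(-2, 2, 121), beta = 1)
  expect_lt(abs(bias_potential(0, st)), 1e-12)  # normalized omega, e^0 = 1
  stream <- rng_stream(22L)
  st$log_omega <- stream_draw(stream, function() rnorm(121, sd = 0.5))
  st$log_omega <- st$log_omega - logsumexp(log(st$grid$weights) + st$log_omega)
  h <- 1e-5
  for (q in c(-1.7, -0.2, 0.9, 3.1)) {
    dv <- (bias_potential(q + h, st) - bias_potential(q - h, st)) / (2 * h)
    expect_lt(abs(-dv - fbar(q, st)) / max(abs(fbar(q, st)), 1e-8), 1e-6)
  }
})

test_that("observable weights follow the mixture formula", {
  st <- fisst_state(force_grid(-2, 2, 121), beta = 1)
  # Q = 0: numerator and normalized mixture are both 1
  for (F in c(-2, -0.5, 0, 1.7)) {
    expect_equal(observable_weight(0, F, st), 1)
  }
  # closed form at Q = 1, F = 2 with uniform omega
  w_exact <- exp(2) / ((exp(2) - exp(-2)) / 4)
  expect_lt(abs(observable_weight(1, 2, st) - w_exact) / w_exact, 1e-3)
  expect_gt(observable_weight(-5, 2, st), 0)
  expect_error(observable_weight(1, 2.5, st), "outside")
  expect_error(observable_weight(1, -9, st), "outside")
})

test_that("weight updates learn 1/Z on iid mixture samples and stay normalized", {
  st <- fisst_state(force_grid(-2, 2, 121), beta = 1)
  orc <- harmonic_oracle()
  md <- mixture_density(orc, st)
  set.seed(7)
  cdf <- cumsum(md$density)
  cdf <- cdf / max(cdf)
  keep <- !duplicated(cdf)
  qs <- approx(cdf[keep], md$q[keep], runif(2e4), rule = 2)$y
  st2 <- update_weights(st, qs)
  target <- harmonic_omega_target(st2$grid)
  expect_lt(max(abs(exp(st2$log_omega) - target) / target), 0.02)
  expect_equal(sum(st2$grid$weights * exp(st2$log_omega)), 1)
  expect_identical(st2$n_samples, 20000L)
  # normalization holds after every successive update
  stream <- rng_stream(31L)
  s <- st2
  for (i in 1:5) {
    s <- update_weights(s, stream_draw(stream, function() rnorm(200)))
    expect_equal(sum(s$grid$weights * exp(s$log_omega)), 1)
  }
})

test_that("constant CV samples leave the weights uniform", {
  st <- fisst_state(force_grid(-2, 2, 41), beta = 1)
  s <- update_weights(st, rep(0, 100))
  expect_equal(max(s$log_omega) - min(s$log_omega), 0)
})

test_that("freezing makes updates no-ops and is idempotent", {
  st <- fisst_state(force_grid(-2, 2, 41), beta = 1)
  st <- update_weights(st, rnorm(50))
  fr <- freeze_weights(st)
  expect_true(fr$frozen)
  expect_warning(fr2 <- update_weights(fr, rnorm(50)), "frozen")
  expect_identical(fr2, fr)
  expect_identical(freeze_weights(freeze_weights(st)), freeze_weights(st))
  # fbar and observable weights are unchanged by freezing
  expect_identical(fbar(0.4, fr), fbar(0.4, st))
  expect_identical(observable_weight(0.4, 1, fr), observable_weight(0.4, 1, st))
})

test_that("restart files round-trip bit-exactly and reject corruption", {
  st <- fisst_state(force_grid(-10, 20, 121), beta = 0.7, update_interval = 250L)
  path <- withr::local_tempfile(fileext = ".restart")
  write_fisst_restart(st, path)
  expect_identical(read_fisst_restart(path), st)

  st2 <- freeze_weights(update_weights(st, rnorm(500, sd = 2)))
  write_fisst_restart(st2, path)
  back <- read_fisst_restart(path)
  expect_identical(back$log_omega, st2$log_omega)
  expect_identical(back$log_zsum, st2$log_zsum)
  expect_identical(back$n_samples, st2$n_samples)
  expect_true(back$frozen)

  # continuing to update a restored state is indistinguishable from the original
  more <- rnorm(300)
  st3 <- update_weights(st, rnorm(500, sd = 2))
  write_fisst_restart(st3, path)
  expect_identical(update_weights(read_fisst_restart(path), more),
                   update_weights(st3, more))

  # corruption is a parse error, never a silent reset
  lines <- readLines(path)
  writeLines(lines[1:40], path)
  expect_error(read_fisst_restart(path), "truncated")
  writeLines(sub("^format_version: 1", "format_version: 99", lines), path)
  expect_error(read_fisst_restart(path), "version")
  writeLines(c("garbage", lines[-1]), path)
  expect_error(read_fisst_restart(path), "not a forcetemper")
})

test_that("reweighted averages normalize, reduce and hit the Gaussian mean", {
  tr <- cached("harm_fisst_5e4", function() {
    st <- fisst_state(force_grid(-2, 2, 121), beta = 1)
    fisst_run(harmonic_sys(), st, std_settings(5e4L, seed = 12L))
  })
  tr$one <- 1
  expect_equal(reweighted_average(tr, "one", F = 1.3), 1)
  expect_lt(abs(reweighted_average(tr, "Q", F = 1) - 1),
            3 * block_se(tr$Q, norm_weights(tr, 1), 25L))
  expect_error(reweighted_average(tr, "nope", F = 0), "unknown observable")
  # degenerate grid: reweighting at F0 is the plain average
  trc <- constant_force_run(harmonic_sys(), 0.8, std_settings(2000L, seed = 13L))
  expect_equal(reweighted_average(trc, "Q", F = 0.8), mean(trc$Q))
})

test_that("every MD step contributes exactly one sample at the update cadence", {
  st <- fisst_state(force_grid(-2, 2, 41), beta = 1, update_interval = 100L)
  tr <- fisst_run(harmonic_sys(), st, std_settings(2000L, seed = 14L))
  fin <- final_fisst_state(tr)
  expect_identical(fin$n_samples, 2000L)
  expect_identical(fin$n_updates, 20L)
})
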