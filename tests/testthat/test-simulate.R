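test_that("discrete trajectories respect the state space of the motif", {
  p <- network_params()
  ns <- noise_spec("sine_wiener", B = 0.5, tau = 10)
  tr <- simulate_exact(p, ns, t_end = 200, seed = 11)
  expect_true(all(tr$gene %in% 0:2))
  expect_true(all(tr$protein >= 0))
  expect_true(all(tr$protein == round(tr$protein)))
  expect_true(all(abs(tr$xi) <= 0.5))
  st <- trajectory_stats(tr)
  expect_gt(st$sum_w, 0)
  expect_equal(sum(st$density$prob), 1, tolerance = 1e-12)

  tr3 <- simulate_slow_gene(p, ns, t_end = 200, seed = 12)
  expect_true(all(tr3$gene %in% 0:2))
  expect_true(all(tr3$protein >= 0))
})

test_that("simulations are reproducible from the seed alone", {
  p <- network_params()
  ns <- noise_spec("cai_lin", B = 0.3, tau = 10, z = -0.5)
  for (r in 1:4) {
    a <- simulate_motif(r, p, ns, t_end = 50, seed = 21)
    b <- simulate_motif(r, p, ns, t_end = 50, seed = 21)
    expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  }
})

test_that("with the gene never closing the protein level relaxes to
           s*n/d", {
  p <- network_params(b0 = 0)
  tr <- simulate_mean_field(p, t_end = 100, y0 = 0)
  expect_equal(tr$protein[nrow(tr)], 6.4, tolerance = 1e-6)
})

test_that("without feedback every regime reproduces the linear birth-death
           mean s*omega*n*c0/((c0+b0)*d)", {
  p <- network_params(c2 = 0)
  target <- 3.2 * 6.022 * 2 / 16          # = 2.4088 protein copies
  e1 <- run_ensemble(1, p, NULL, n_runs = 10, t_end = 2e3, seed = 31)
  expect_equal(e1$mean, target, tolerance = 0.05)
  e2 <- run_ensemble(2, p, NULL, n_runs = 10, t_end = 2e3, seed = 32)
  expect_equal(e2$mean, target, tolerance = 0.05)
  tr4 <- simulate_mean_field(p, t_end = 100, y0 = 0)
  expect_equal(tr4$protein[nrow(tr4)], target / 6.022, tolerance = 1e-6)
})

test_that("the exact sampler matches the stationary law of the truncated
           master equation on a small motif", {
  # toy motif small enough to solve the generator null space directly
  p <- network_params(h = 1, c0_base = 1, n = 1, s = 1, d = 1, omega = 1,
                      c0 = 1, c2 = 1, b0 = 2)
  ymax <- 14
  idx <- function(G, Y) G * (ymax + 1) + Y + 1
  nstate <- 2 * (ymax + 1)
  Q <- matrix(0, nstate, nstate)
  for (G in 0:1) {
    for (Y in 0:ymax) {
      i <- idx(G, Y)
      if (G == 1) Q[i, idx(0, Y)] <- 2                 # deactivation b0*G
      if (G == 0) Q[i, idx(1, Y)] <- 1 + Y^2           # activation c(y)
      if (G == 1 && Y < ymax) Q[i, idx(1, Y + 1)] <- 1 # birth s*omega*G
      if (Y > 0) Q[i, idx(G, Y - 1)] <- Y              # death d*Y
    }
  }
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, nstate))
  pi_hat <- qr.solve(A, c(rep(0, nstate), 1))
  pi_y <- vapply(0:ymax, function(Y) pi_hat[idx(0, Y)] + pi_hat[idx(1, Y)],
                 numeric(1))

  hist <- list(lo = -0.5, hi = ymax + 0.5, nbins = ymax + 1L)
  es <- run_ensemble(1, p, NULL, n_runs = 20, t_end = 2e3, seed = 41,
                     hist = hist)
  expect_lt(max(abs(es$density$prob - pi_y)), 0.02)
  expect_equal(es$mean, sum((0:ymax) * pi_y), tolerance = 0.05)
})

test_that("quasi-static and thinning samplers of the exact model agree in
           distribution", {
  p <- network_params()
  ns <- noise_spec("sine_wiener", B = 0.5, tau = 10)
  m_qs <- run_ensemble(1, p, ns, n_runs = 15, t_end = 1e3, seed = 51,
                       method = "quasi_static")$run_means
  m_th <- run_ensemble(1, p, ns, n_runs = 15, t_end = 1e3, seed = 52,
                       method = "thinning")$run_means
  expect_gt(suppressWarnings(stats::ks.test(m_qs, m_th)$p.value), 0.01)
})

test_that("hazard-inversion and thinning samplers of the piecewise-
           deterministic model agree in distribution", {
  p <- network_params()
  ns <- noise_spec("sine_wiener", B = 0.3, tau = 10)
  m_hz <- run_ensemble(3, p, ns, n_runs = 15, t_end = 1e3, seed = 61,
                       method = "hazard")$run_means
  m_th <- run_ensemble(3, p, ns, n_runs = 15, t_end = 1e3, seed = 62,
                       method = "thinning")$run_means
  expect_gt(suppressWarnings(stats::ks.test(m_hz, m_th)$p.value), 0.01)
})

test_that("the noise-free mean-field flow is attracted to the equilibrium
           on its side of the separatrix", {
  p <- network_params(h = 100)
  fp <- fixed_points(p)
  y_l <- fp$y[1]; y_u <- fp$y[2]; y_h <- fp$y[3]
  below <- simulate_mean_field(p, t_end = 100, y0 = y_u - 0.05)
  above <- simulate_mean_field(p, t_end = 100, y0 = y_u + 0.05)
  expect_equal(below$protein[nrow(below)], y_l, tolerance = 1e-6)
  expect_equal(above$protein[nrow(above)], y_h, tolerance = 1e-6)
})

test_that("simulators validate their initial conditions and horizons", {
  p <- network_params()
  expect_error(simulate_exact(p, init = list(G = 3, Y = 0)), "G")
  expect_error(simulate_exact(p, init = list(G = 0, Y = -1)))
  expect_error(simulate_slow_gene(p, init = list(G = -1, y = 0)), "G")
  expect_error(simulate_mean_field(p, y0 = -1), "y0")
  expect_error(simulate_mean_field(p, t_end = 0), "t_end")
  expect_error(simulate_fast_gene(p, init = list(Y = 0, G_mean = 5)))
})
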