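# Kolmogorov-Smirnov distance of pooled values against a closed-form CDF
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  f <- cdf(x)
  max(abs(f - seq_len(n) / n), abs(f - (seq_len(n) - 1) / n))
}

test_that("bounded noise paths never leave [-B, B]", {
  sw <- noise_spec("sine_wiener", B = 0.7, tau = 1)
  cl <- noise_spec("cai_lin", B = 0.7, tau = 1, z = -0.5)
  p1 <- sample_noise(sw, t_end = 50, seed = 1)
  p2 <- sample_noise(cl, t_end = 50, seed = 2)
  expect_true(all(abs(p1$xi) <= 0.7))
  expect_true(all(abs(p2$xi) <= 0.7))
  # Cai-Lin diffusion coefficient vanishes at the boundary; the clamped
  # Euler-Maruyama step must keep |xi| strictly inside the support
  expect_true(all(abs(p2$xi) < 0.7))
})

test_that("long-run sine-Wiener values follow the arcsine law", {
  sw <- noise_spec("sine_wiener", B = 0.8, tau = 1)
  set.seed(101)
  vals <- unlist(lapply(1:100, function(i) {
    x <- sample_noise_values(sw, n_steps = 1e5, dt = noise_dt(sw))
    x[-seq_len(1000)]          # drop the xi(0) = 0 transient (10 tau)
  }))
  d <- ks_distance(vals, function(q) noise_stationary_cdf(q, sw))
  expect_lt(d, 0.02)
})

test_that("Cai-Lin values follow the Beta-type stationary law for both
           horn- and bell-shaped cases", {
  for (z in c(-0.5, 0.5)) {
    cl <- noise_spec("cai_lin", B = 0.9, tau = 1, z = z)
    set.seed(200 + round(10 * z))
    vals <- unlist(lapply(1:100, function(i) {
      sample_noise_values(cl, n_steps = 1e5, dt = noise_dt(cl))
    }))
    d <- ks_distance(vals, function(q) noise_stationary_cdf(q, cl))
    expect_lt(d, 0.02)
  }
})

test_that("the perturbation is unbiased: the deactivation rate keeps its
           baseline average", {
  cl <- noise_spec("cai_lin", B = 0.9, tau = 1, z = -0.5)
  set.seed(33)
  path_means <- vapply(1:100, function(i) {
    mean(sample_noise_values(cl, n_steps = 2e4, dt = noise_dt(cl)))
  }, numeric(1))
  se <- stats::sd(path_means) / sqrt(length(path_means))
  expect_lt(abs(mean(path_means)), 4 * se)
})

test_that("zero amplitude consumes no random numbers and is bit-identical
           to the noise-free system", {
  set.seed(7)
  before <- .Random.seed
  p <- sample_noise(noise_spec("sine_wiener", B = 0, tau = 1), t_end = 5)
  expect_identical(.Random.seed, before)
  expect_true(all(p$xi == 0))

  params <- network_params()
  t_a <- simulate_exact(params, noise = NULL, t_end = 50, seed = 3)
  t_b <- simulate_exact(params,
                        noise = noise_spec("cai_lin", B = 0, tau = 10,
                                           z = -0.5),
                        t_end = 50, seed = 3)
  for (col in c("time", "gene", "protein", "xi")) {
    expect_identical(t_a[[col]], t_b[[col]])
  }
})

test_that("noise autocovariance decays with lag", {
  cl <- noise_spec("cai_lin", B = 0.9, tau = 0.1, z = 0.5)
  p <- sample_noise(cl, t_end = 200, seed = 17)
  st <- empirical_noise_stats(p, lags = c(0, 50, 400))
  acov <- st$autocovariance$acov
  expect_gt(acov[1], 0)
  # lag 400 steps = 4 tau: correlation must have dropped substantially
  expect_lt(acov[3], 0.25 * acov[1])
})

test_that("noise specifications reject out-of-range parameters", {
  expect_error(noise_spec("sine_wiener", B = 1.5, tau = 1), "B")
  expect_error(noise_spec("sine_wiener", B = -0.1, tau = 1), "B")
  expect_error(noise_spec("sine_wiener", B = 0.5, tau = 0), "tau")
  expect_error(noise_spec("cai_lin", B = 0.5, tau = 1, z = -1), "z")
  expect_error(sample_noise(noise_spec("sine_wiener", B = 0.1, tau = 1),
                            t_end = -1), "t_end")
})

test_that("noise histograms are supported on [-B, B] and normalised", {
  cl <- noise_spec("cai_lin", B = 0.4, tau = 1, z = 0.5)
  paths <- lapply(1:5, function(i) sample_noise(cl, t_end = 50, seed = i))
  st <- empirical_noise_stats(paths, bins = 40)
  h <- st$histogram
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  expect_gte(min(h$bin_left), -0.4)
  expect_lte(max(h$bin_right), 0.4)
})
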