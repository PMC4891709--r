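test_that("derived seeds are deterministic and distinct across runs", {
  s1 <- vapply(1:100, function(i) derive_seed(1, i), integer(1))
  s2 <- vapply(1:100, function(i) derive_seed(1, i), integer(1))
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 100L)
  expect_false(derive_seed(1, 1) == derive_seed(2, 1))
})

test_that("pooled stationary densities are normalised and ensembles are
           reproducible", {
  p <- network_params()
  ns <- noise_spec("sine_wiener", B = 0.3, tau = 10)
  a <- run_ensemble(1, p, ns, n_runs = 5, t_end = 500, seed = 71)
  b <- run_ensemble(1, p, ns, n_runs = 5, t_end = 500, seed = 71)
  expect_equal(sum(a$density$prob), 1, tolerance = 1e-12)
  expect_identical(a$mean, b$mean)
  expect_identical(a$density, b$density)
  expect_identical(a$run_means, b$run_means)
  g <- generics::glance(a)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n_runs, 5L)
  expect_error(run_ensemble(1, p, ns, n_runs = 0), "n_runs")
  expect_error(run_ensemble(1, p, ns, t_end = 10, burn_in = 10), "burn_in")
})

test_that("point-mass densities are classified by mode count and location
           relative to the unstable equilibrium", {
  p <- network_params(h = 100)
  edges <- seq(0, 5.2, length.out = 105)
  mk <- function(masses) {
    prob <- rep(0, 104)
    for (m in names(masses)) {
      i <- findInterval(as.numeric(m), edges)
      prob[i] <- masses[[m]]
    }
    tibble::tibble(bin_left = edges[-105], bin_right = edges[-1],
                   prob = prob / sum(prob))
  }
  expect_equal(classify_modality(mk(list("0.627" = 1)), p, 4),
               "unimodal_low")
  expect_equal(classify_modality(mk(list("4.28" = 1)), p, 4),
               "unimodal_high")
  expect_equal(classify_modality(mk(list("0.627" = 1, "4.28" = 1)), p, 4),
               "bimodal")
  # a shallow dip (minimum above half the smaller mode) is not bimodality:
  # plateau at 0.8 between bumps of height 1, dip/smaller = 0.8 > 0.5
  centers <- 0.5 * (edges[-105] + edges[-1])
  shallow <- tibble::tibble(
    bin_left = edges[-105], bin_right = edges[-1],
    prob = 0.8 + 0.2 * (abs(centers - 0.627) < 0.1) +
      0.2 * (abs(centers - 4.28) < 0.1))
  shallow$prob <- shallow$prob / sum(shallow$prob)
  expect_false(classify_modality(shallow, p, 4) == "bimodal")
  empty <- tibble::tibble(bin_left = 0, bin_right = 1, prob = 0)
  expect_error(classify_modality(empty, p, 4), "empty")
})

test_that("the first-order detector never fires on constant rows", {
  set.seed(81)
  fired <- 0L
  for (k in 1:1000) {
    row <- tibble::tibble(B = seq(0.02, 0.12, by = 0.01),
                          mean = 4.2 + rnorm(11, 0, 0.05),
                          se = 0.05, sd = runif(11, 0.1, 0.3))
    if (!is.null(detect_first_order(row))) fired <- fired + 1L
    if (!is.null(detect_first_order(row, classes = NULL))) {
      fired <- fired + 1L
    }
  }
  expect_equal(fired, 0L)
})

test_that("the first-order detector locates a synthetic low-to-high step
           at its midpoint", {
  row <- tibble::tibble(B = seq(0.02, 0.12, by = 0.01),
                        mean = c(rep(0.63, 6), rep(4.2, 5)),
                        se = 0.02,
                        sd = c(rep(0.1, 5), 0.9, rep(0.3, 5)))
  hit <- detect_first_order(row)
  expect_false(is.null(hit))
  expect_equal(hit$B_transition, 0.5 * (0.07 + 0.08))
  expect_gt(hit$jump, 3)
  expect_true(hit$sigma_peak)
  # a mixture cell between the classes must not hide the transition
  row$mean[7] <- 1.8
  hit2 <- detect_first_order(row)
  expect_equal(hit2$B_transition, 0.5 * (0.07 + 0.09))
})

test_that("the second-order detector reports the smallest bimodal
           amplitude with its variance cross-check", {
  row <- tibble::tibble(B = seq(0.1, 0.2, by = 0.01),
                        modality = c(rep("unimodal_high", 6),
                                     rep("bimodal", 5)),
                        sd = seq(0.2, 1.2, length.out = 11))
  hit <- detect_second_order(row)
  expect_equal(hit$B_onset, 0.16)
  expect_true(hit$sd_growing)
  none <- tibble::tibble(B = c(0.1, 0.2),
                         modality = c("unimodal_high", "unimodal_high"),
                         sd = c(0.2, 0.2))
  expect_null(detect_second_order(none))
})

test_that("a single-cell sweep equals a direct ensemble call", {
  p <- network_params(h = 100)
  pd <- sweep_phase_diagram(4, p, "sine_wiener", B_grid = 0.05,
                            facet = list(tau = 10),
                            ic_sampler = ic_fixed(0.3), n_runs = 5,
                            t_end = 500, seed = 9)
  direct <- run_ensemble(4, p, noise_spec("sine_wiener", B = 0.05,
                                          tau = 10),
                         ic_sampler = ic_fixed(0.3), n_runs = 5,
                         t_end = 500, seed = derive_seed(9, 1))
  expect_equal(pd$mean, direct$mean)
  expect_equal(pd$sd, direct$sd)
  expect_equal(pd$modality, direct$modality)
  expect_s3_class(generics::tidy(pd), "tbl_df")
  expect_equal(generics::glance(pd)$n_cells, 1L)
})

test_that("phase diagrams and densities export as tidy CSV artifacts", {
  p <- network_params(h = 100)
  pd <- sweep_phase_diagram(4, p, "sine_wiener", B_grid = c(0.02, 0.05),
                            facet = list(tau = 10),
                            ic_sampler = ic_fixed(0.3), n_runs = 3,
                            t_end = 300, seed = 10)
  f <- tempfile(fileext = ".csv")
  write_phase_diagram_csv(pd, f)
  got <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(names(got),
               c("regime", "B", "tau", "omega", "mean", "sd", "modality"))
  expect_equal(nrow(got), 2L)
  fd <- tempfile(fileext = ".csv")
  write_density_csv(pd$summary[[1]], fd)
  d <- readr::read_csv(fd, show_col_types = FALSE)
  expect_equal(sum(d$prob), 1, tolerance = 1e-9)
})

test_that("autoplot methods return ggplot objects for every result type", {
  p <- network_params(h = 100)
  tr <- simulate_mean_field(p, t_end = 50, y0 = 0.3)
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
  es <- run_ensemble(4, p, NULL, ic_sampler = ic_fixed(0.3), n_runs = 2,
                     t_end = 300, seed = 2)
  expect_s3_class(ggplot2::autoplot(es), "ggplot")
  pd <- sweep_phase_diagram(4, p, "sine_wiener", B_grid = c(0.02, 0.05),
                            facet = list(tau = 10),
                            ic_sampler = ic_fixed(0.3), n_runs = 2,
                            t_end = 300, seed = 3)
  expect_s3_class(ggplot2::autoplot(pd), "ggplot")
  hs <- hysteresis_scan(p, seq(10, 20, by = 1))
  expect_s3_class(ggplot2::autoplot(hs), "ggplot")
})
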