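# independent oracle: the steady states solve the cubic
# d*r2*y^3 - s*n*r2*y^2 + d*(1 + R)*y - s*n = 0 with r2 = c2/c0, R = b0/c0
cubic_roots <- function(params, R = params$b0 / params$c0) {
  r2 <- params$c2 / params$c0
  s <- params$s; n <- params$n; d <- params$d
  z <- polyroot(c(-s * n, d * (1 + R), -s * n * r2, d * r2))
  re <- Re(z[abs(Im(z)) < 1e-8])
  sort(re[re >= 0])
}

test_that("fixed points agree with the cubic steady-state equation to
           well below 4 significant figures", {
  p <- network_params()
  fp <- fixed_points(p)
  expect_equal(nrow(fp), 3L)
  expect_equal(fp$y, cubic_roots(p), tolerance = 1e-8)
  expect_equal(fp$stability, c("stable", "unstable", "stable"))
  # residual of the flow at every reported root
  rhs <- function(y) {
    cy <- p$c0 + p$c2 * y^2
    p$s * p$n * cy / (cy + p$b0) - p$d * y
  }
  expect_true(all(abs(rhs(fp$y)) < 1e-10))
})

test_that("without deactivation the gene stays on and the protein level
           saturates at s*n/d", {
  p <- network_params()
  fp <- fixed_points(p, b0_over_c0 = 0)
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$y, 6.4, tolerance = 1e-8)
  expect_equal(fp$stability, "stable")
})

test_that("overwhelming deactivation leaves a single low equilibrium", {
  p <- network_params()
  fp <- fixed_points(p, b0_over_c0 = 1000)
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$y, cubic_roots(p, R = 1000), tolerance = 1e-8)
  expect_lt(fp$y, 0.01)
})

test_that("removing the feedback removes bistability", {
  p <- network_params(c2 = 0)
  fp <- fixed_points(p)
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$y, 3.2 * 2 / 16, tolerance = 1e-10)   # s*n*c0/((c0+b0)*d)
  hs <- hysteresis_scan(p, seq(5, 30, by = 1))
  expect_null(attr(hs, "bistable_interval"))
})

test_that("the hysteresis folds bracket the bistable interval found by an
           independent root-count bisection", {
  p <- network_params()
  hs <- hysteresis_scan(p, seq(10, 20, by = 0.5))
  iv <- attr(hs, "bistable_interval")
  expect_false(is.null(iv))
  # oracle: bisect the root count of the cubic directly
  count3 <- function(R) length(cubic_roots(p, R)) == 3
  bisect <- function(lo, hi, want_hi) {
    for (k in 1:60) {
      mid <- 0.5 * (lo + hi)
      if (count3(mid) == want_hi) hi <- mid else lo <- mid
    }
    0.5 * (lo + hi)
  }
  lower <- bisect(10, 15, want_hi = TRUE)
  upper <- bisect(16, 20, want_hi = FALSE)
  expect_equal(unname(iv[["lower"]]), lower, tolerance = 1e-4)
  expect_equal(unname(iv[["upper"]]), upper, tolerance = 1e-4)
  # the deterministic transition amplitudes implied by the folds:
  # b0*(1-B) crosses the lower fold near B = 0.066, b0*(1+B) the upper
  # fold near B = 0.166
  expect_equal(1 - lower / 15, 0.066, tolerance = 0.05)
  expect_equal(upper / 15 - 1, 0.166, tolerance = 0.05)
})

test_that("branch stabilities alternate along the bifurcation diagram", {
  p <- network_params()
  hs <- hysteresis_scan(p, seq(14.5, 17, by = 0.5))
  per_ratio <- split(hs$stability, hs$b0_over_c0)
  for (st in per_ratio) {
    expect_equal(st, c("stable", "unstable", "stable"))
  }
  expect_error(hysteresis_scan(p, c(2, 1, 3)), "ascending")
})

test_that("tidy and glance summarise deterministic results as tibbles", {
  p <- network_params()
  fp <- fixed_points(p)
  expect_s3_class(generics::tidy(fp), "tbl_df")
  g <- generics::glance(fp)
  expect_true(g$bistable)
  expect_equal(g$b0_over_c0, 15)
  hs <- hysteresis_scan(p, seq(10, 20, by = 1))
  gh <- generics::glance(hs)
  expect_true(gh$bistable)
  expect_lt(gh$fold_lower, gh$fold_upper)
})
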