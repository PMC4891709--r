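#' Simulate the motif in one of the four model regimes
#'
#' A single front door over the four regime-specific samplers:
#'
#' | regime | gene switching | proteins | model |
#' |--------|----------------|----------|-------|
#' | 1 | slow | few  | exact time-inhomogeneous birth-death for `(G, Y)` |
#' | 2 | fast | few  | birth-death for `Y` driven by the gene mean |
#' | 3 | slow | many | piecewise-deterministic process for `(G, y)` |
#' | 4 | fast | many | mean-field ODE for `y` |
#'
#' All regimes share the same bounded-noise deactivation rate
#' `b0(t) = b0 (1 + xi(t))`. See [simulate_exact()],
#' [simulate_fast_gene()], [simulate_slow_gene()], [simulate_mean_field()]
#' for the regime-specific arguments.
#'
#' @param regime Integer 1-4.
#' @param params A [network_params()] object.
#' @param noise A [noise_spec()] or `NULL` for the noise-free system.
#' @param init Initial condition (regime-specific; see the regime
#'   functions for defaults).
#' @param t_end Simulation horizon in dimensionless time.
#' @param seed Optional integer seed.
#' @param ... Passed to the regime-specific simulator.
#' @return A `motif_trajectory` tibble.
#' @export
simulate_motif <- function(regime, params, noise = NULL, init = NULL,
                           t_end = 1e4, seed = NULL, ...) {
  switch(as.character(regime),
    "1" = simulate_exact(params, noise, init = init, t_end = t_end,
                         seed = seed, ...),
    "2" = simulate_fast_gene(params, noise, init = init, t_end = t_end,
                             seed = seed, ...),
    "3" = simulate_slow_gene(params, noise, init = init, t_end = t_end,
                             seed = seed, ...),
    "4" = simulate_mean_field(params, noise,
                              y0 = if (is.null(init)) 0
                                   else if (is.list(init))
                                     init[["y"]] %||% init[["Y"]]
                                   else init,
                              t_end = t_end, seed = seed, ...),
    abort("`regime` must be 1, 2, 3 or 4.")
  )
}

# noise = NULL means the noise-free system: a zero path that consumes no
# random numbers, so it is bit-identical to a B = 0 run at the same seed
resolve_noise <- function(noise) {
  if (is.null(noise)) noise_spec("sine_wiener", B = 0, tau = 1) else noise
}

# default histogram geometry: integer bins for protein counts in small
# volumes, 100 uniform bins over [0, 1.2 * y_H] (times omega for counts)
# otherwise
default_hist <- function(regime, params) {
  y_top <- if (params$c0 > 0) {
    max(fixed_points(params)$y)
  } else {
    params$s * params$n / params$d
  }
  if (regime %in% c(1L, 2L)) {
    if (params$omega <= 60.22) {
      ymax <- ceiling(1.5 * params$s * params$n * params$omega / params$d)
      list(lo = -0.5, hi = ymax + 0.5, nbins = as.integer(ymax + 1))
    } else {
      list(lo = 0, hi = 1.2 * y_top * params$omega, nbins = 100L)
    }
  } else {
    list(lo = 0, hi = 1.2 * y_top, nbins = 100L)
  }
}

new_trajectory <- function(res, regime, params, noise, seed, method,
                           burn_in, hist) {
  out <- tibble::tibble(time = res$time, gene = res$gene,
                        protein = res$protein, xi = res$xi)
  class(out) <- c("motif_trajectory", class(out))
  edges <- seq(hist$lo, hist$hi, length.out = hist$nbins + 1)
  w <- res$sum_w
  stats <- list(
    sum_w = w, sum_x = res$sum_x, sum_x2 = res$sum_x2,
    mean = if (w > 0) res$sum_x / w else NA_real_,
    sd = if (w > 0) {
      sqrt(max(res$sum_x2 / w - (res$sum_x / w)^2, 0))
    } else NA_real_,
    density = tibble::tibble(
      bin_left = edges[-length(edges)], bin_right = edges[-1],
      prob = if (sum(res$hist) > 0) res$hist / sum(res$hist) else res$hist
    )
  )
  attr(out, "regime") <- regime
  attr(out, "params") <- params
  attr(out, "noise") <- noise
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  attr(out, "burn_in") <- burn_in
  attr(out, "stats") <- stats
  out
}

#' @export
print.motif_trajectory <- function(x, ...) {
  st <- attr(x, "stats")
  cat("<motif_trajectory> regime", attr(x, "regime"),
      "| method", attr(x, "method") %||% "-",
      "| post-burn-in mean", signif(st$mean, 4),
      "sd", signif(st$sd, 4), "\n")
  NextMethod()
}

#' Long-run statistics of a simulated trajectory
#'
#' Time-weighted (occupation-measure) mean, standard deviation and
#' histogram of the protein variable after the burn-in window, as
#' accumulated during simulation.
#' @param traj A `motif_trajectory`.
#' @return A list with `mean`, `sd`, `density` (tibble `bin_left`,
#'   `bin_right`, `prob`) and the raw weighted sums.
#' @export
trajectory_stats <- function(traj) {
  attr(traj, "stats")
}

#' Exact simulation of the slow-switching, few-protein regime
#'
#' The full discrete state `(G, Y)` evolves as a time-inhomogeneous
#' birth-death process with the five propensities of [propensities()].
#' Two statistically equivalent samplers are provided:
#'
#' * `"quasi_static"`: the noise is piecewise constant on its own grid,
#'   and the standard Gillespie algorithm runs within each grid cell
#'   (exact for the piecewise-constant path, justified by the wide
#'   separation between network and noise time scales).
#' * `"thinning"`: candidate events at the bound rate obtained by
#'   replacing the deactivation propensity with `b0 (1 + B) G`, accepted
#'   with probability `a(t) / a_bound`.
#'
#' @inheritParams simulate_motif
#' @param init Named list with `G` (active gene copies) and `Y` (protein
#'   copies); a bare number is taken as `Y` with the gene initially
#'   inactive. Default `G = 0, Y = 0`.
#' @param method `"quasi_static"` or `"thinning"`.
#' @param burn_in Time discarded from the accumulated statistics
#'   (default 20% of `t_end`).
#' @param record_dt Spacing of recorded trajectory points (default 1).
#' @param hist Histogram geometry `list(lo, hi, nbins)`; a sensible
#'   default is derived from the parameters.
#' @return A `motif_trajectory` tibble with columns `time`, `gene`
#'   (active gene count), `protein` (copy number `Y`) and `xi`.
#' @export
simulate_exact <- function(params, noise = NULL, init = NULL, t_end = 1e4,
                           seed = NULL,
                           method = c("quasi_static", "thinning"),
                           burn_in = 0.2 * t_end, record_dt = 1,
                           hist = NULL) {
  method <- match.arg(method)
  noise <- resolve_noise(noise)
  if (is.null(init)) init <- list(G = 0, Y = 0)
  if (!is.list(init)) init <- list(G = 0, Y = init)
  G0 <- as.integer(init[["G"]] %||% 0); Y0 <- as.numeric(init[["Y"]])
  check_init_discrete(G0, Y0, params)
  if (t_end <= 0) abort("`t_end` must be positive.")
  if (!is.null(seed)) set.seed(seed)
  dtn <- noise_dt(noise)
  xi <- sample_noise_values(noise, ceiling(t_end / dtn), dtn)
  hist <- hist %||% default_hist(1L, params)
  res <- cpp_sim_regime1(params$n, params$s, params$d, params$c0,
                         params$c2, params$b0, noise$B, params$omega,
                         xi, dtn, t_end, burn_in, G0, Y0,
                         if (method == "quasi_static") 0L else 1L,
                         record_dt, hist$lo, hist$hi, hist$nbins)
  new_trajectory(res, 1L, params, noise, seed, method, burn_in, hist)
}

#' Hybrid simulation of the fast-switching, few-protein regime
#'
#' Protein copies `Y` follow a birth-death process with birth rate
#' `s omega <G(t)>` and death rate `d Y`, where the gene mean is either
#' the fast-switching quasi-steady state
#' `<G> = n c(y) / (c(y) + b0(t))` evaluated at the current `y = Y/omega`
#' (`gene_mode = "qss"`, the `h -> Inf` limit of the gene master
#' equation), or the finite-h relaxation
#' `d<G>/dt = c(y)(n - <G>) - b0(t) <G>` (`gene_mode = "relax"`, for
#' robustness checks). Birth events are sampled by thinning with the
#' bound `s omega n`.
#'
#' @inheritParams simulate_exact
#' @param init Named list with `Y` (protein copies) and `G_mean` (initial
#'   gene mean, used by the relaxation mode); a bare number is taken as
#'   `Y`. Default both 0.
#' @param gene_mode `"qss"` or `"relax"`.
#' @return A `motif_trajectory` with `gene` holding the gene mean.
#' @export
simulate_fast_gene <- function(params, noise = NULL, init = NULL,
                               t_end = 1e4, seed = NULL,
                               gene_mode = c("qss", "relax"),
                               burn_in = 0.2 * t_end, record_dt = 1,
                               hist = NULL) {
  gene_mode <- match.arg(gene_mode)
  noise <- resolve_noise(noise)
  if (is.null(init)) init <- list(Y = 0, G_mean = 0)
  if (!is.list(init)) init <- list(Y = init, G_mean = 0)
  Y0 <- as.numeric(init[["Y"]])
  Gm0 <- as.numeric(init[["G_mean"]] %||% 0)
  if (Y0 < 0 || Gm0 < 0 || Gm0 > params$n) {
    abort("`init` must satisfy Y >= 0 and 0 <= G_mean <= n.")
  }
  if (t_end <= 0) abort("`t_end` must be positive.")
  if (!is.null(seed)) set.seed(seed)
  dtn <- noise_dt(noise)
  xi <- sample_noise_values(noise, ceiling(t_end / dtn), dtn)
  hist <- hist %||% default_hist(2L, params)
  res <- cpp_sim_regime2(params$n, params$s, params$d, params$c0,
                         params$c2, params$b0, xi, dtn, t_end, burn_in,
                         Y0, Gm0, if (gene_mode == "qss") 0L else 1L,
                         params$omega, record_dt,
                         hist$lo, hist$hi, hist$nbins)
  new_trajectory(res, 2L, params, noise, seed, gene_mode, burn_in, hist)
}

#' Piecewise-deterministic simulation of the slow-switching,
#' many-protein regime
#'
#' The gene count `G` jumps with rates `a1 = b0(t) G`,
#' `a2 = c0 (n - G)` and `a3 = c2 y(t)^2 (n - G)`, while between jumps the
#' protein density follows the deterministic flow `dy/dt = s G - d y`
#' (solved in closed form). Next-jump times are drawn either by
#' numerically inverting the integrated hazard along the flow
#' (`method = "hazard"`, stepping on the noise grid) or by thinning with
#' the flow bound `max(y0, s G / d)` on the feedback propensity
#' (`method = "thinning"`); the two must agree in distribution.
#'
#' @inheritParams simulate_exact
#' @param init Named list with `G` (gene count) and `y` (protein
#'   density); a bare number is taken as `y` with the gene initially
#'   inactive. Default `G = 0, y = 0`.
#' @param method `"hazard"` or `"thinning"`.
#' @param hist_step Sub-step used to fill the occupation histogram along
#'   the deterministic flow.
#' @return A `motif_trajectory` with `protein` holding the density `y`.
#' @export
simulate_slow_gene <- function(params, noise = NULL, init = NULL,
                               t_end = 1e4, seed = NULL,
                               method = c("hazard", "thinning"),
                               burn_in = 0.2 * t_end, record_dt = 1,
                               hist = NULL, hist_step = 0.01) {
  method <- match.arg(method)
  noise <- resolve_noise(noise)
  if (is.null(init)) init <- list(G = 0, y = 0)
  if (!is.list(init)) init <- list(G = 0, y = init)
  G0 <- as.integer(init[["G"]] %||% 0); y0 <- as.numeric(init[["y"]])
  check_init_discrete(G0, y0, params)
  if (t_end <= 0) abort("`t_end` must be positive.")
  if (!is.null(seed)) set.seed(seed)
  dtn <- noise_dt(noise)
  xi <- sample_noise_values(noise, ceiling(t_end / dtn), dtn)
  hist <- hist %||% default_hist(3L, params)
  res <- cpp_sim_regime3(params$n, params$s, params$d, params$c0,
                         params$c2, params$b0, noise$B, xi, dtn,
                         t_end, burn_in, G0, y0,
                         if (method == "hazard") 0L else 1L,
                         record_dt, hist$lo, hist$hi, hist$nbins,
                         hist_step)
  new_trajectory(res, 3L, params, noise, seed, method, burn_in, hist)
}

#' Mean-field simulation of the fast-switching, many-protein regime
#'
#' Integrates `dy/dt = s n c(y) / (c(y) + b0(t)) - d y` with
#' `b0(t) = b0 (1 + xi(t))` by fixed-step fourth-order Runge-Kutta, the
#' noise held constant within each step. In the noise-free case this is
#' the classical deterministic positive-feedback model with stable
#' equilibria `y_L` and `y_H` separated by the unstable `y_U` (see
#' [fixed_points()]).
#'
#' @inheritParams simulate_exact
#' @param y0 Initial protein density, `>= 0`.
#' @param dt_ode Integration step; default `min(noise step, 0.01)`.
#' @return A `motif_trajectory` with `protein` holding the density `y`
#'   and `gene` `NA` (the gene mean is slaved to `y`).
#' @export
simulate_mean_field <- function(params, noise = NULL, y0 = 0, t_end = 1e4,
                                seed = NULL, dt_ode = NULL,
                                burn_in = 0.2 * t_end, record_dt = 1,
                                hist = NULL) {
  noise <- resolve_noise(noise)
  if (y0 < 0) abort("`y0` must be nonnegative.")
  if (t_end <= 0) abort("`t_end` must be positive.")
  if (!is.null(seed)) set.seed(seed)
  dtn <- noise_dt(noise)
  dt_ode <- dt_ode %||% min(dtn, 0.01)
  xi <- sample_noise_values(noise, ceiling(t_end / dtn), dtn)
  hist <- hist %||% default_hist(4L, params)
  res <- cpp_sim_regime4(params$n, params$s, params$d, params$c0,
                         params$c2, params$b0, xi, dtn, t_end, burn_in,
                         y0, dt_ode, record_dt,
                         hist$lo, hist$hi, hist$nbins)
  new_trajectory(res, 4L, params, noise, seed, "rk4", burn_in, hist)
}

check_init_discrete <- function(G0, Y0, params) {
  if (is.na(G0) || G0 < 0 || G0 > params$n) {
    abort("initial `G` must be an integer in 0..n.")
  }
  if (is.na(Y0) || Y0 < 0) abort("initial protein level must be >= 0.")
  invisible(TRUE)
}

#' Write a trajectory to CSV
#'
#' Columns `time`, `gene`, `protein`, `xi`.
#' @param traj A `motif_trajectory`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(traj, file) {
  readr::write_csv(tibble::as_tibble(traj), file)
  invisible(file)
}
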