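#' Derive a reproducible sub-stream seed
#'
#' One root seed per experiment; per-run (and per-cell) seeds are derived
#' by a counter so ensembles are reproducible and order-independent. The
#' result always fits a 32-bit integer.
#'
#' @param root Root integer seed.
#' @param ... Integer counters (run index, cell index, ...).
#' @return An integer seed.
#' @export
derive_seed <- function(root, ...) {
  idx <- c(...)
  x <- abs(as.double(root)) %% 2147483647
  for (i in idx) x <- (x * 48271 + as.double(i) * 9973 + 1) %% 2147483647
  as.integer(x)
}

#' Initial-condition samplers
#'
#' Helpers returning functions that draw one initial condition per run
#' (using the run's RNG sub-stream, so ensembles are reproducible).
#' `ic_uniform_y` draws the protein level uniformly on `[lo, hi]`
#' (continuous, for the density regimes); `ic_uniform_count` draws an
#' integer copy number uniformly on `{lo, ..., hi}`; `ic_fixed` always
#' returns the same value.
#'
#' @param lo,hi Range bounds.
#' @param G,G_mean Initial gene state passed through to the simulator.
#' @param value Fixed initial condition for `ic_fixed`.
#' @return A function of no arguments returning an initial condition in
#'   the shape the target regime expects.
#' @name ic_samplers
NULL

#' @rdname ic_samplers
#' @export
ic_uniform_y <- function(lo = 0, hi = 1) {
  force(lo); force(hi)
  function() runif(1, lo, hi)
}

#' @rdname ic_samplers
#' @export
ic_uniform_count <- function(lo = 0, hi = 100, G = 0, G_mean = 0) {
  force(lo); force(hi); force(G); force(G_mean)
  function() {
    list(Y = sample(seq.int(lo, hi), 1L), G = G, G_mean = G_mean,
         y = runif(1, lo, hi))
  }
}

#' @rdname ic_samplers
#' @export
ic_fixed <- function(value) {
  force(value)
  function() value
}

#' Ensemble estimate of the stationary protein law
#'
#' Runs `n_runs` independent trajectories of the chosen regime, pools the
#' time-weighted occupation measure of the protein variable after the
#' burn-in window across runs, and summarises it as a stationary density
#' histogram, long-run mean and standard deviation, and a modality label
#' (see [classify_modality()]). Jump regimes are weighted by holding
#' times (continuous-time occupation measure); the ODE regime by its
#' uniform integration grid.
#'
#' @param regime Integer 1-4.
#' @param params A [network_params()] object.
#' @param noise A [noise_spec()] or `NULL`.
#' @param ic_sampler A function of no arguments drawing one initial
#'   condition per run (see [ic_samplers]); default starts from the empty
#'   state.
#' @param n_runs Number of independent runs.
#' @param t_end Horizon per run.
#' @param burn_in Discarded initial window (default 20% of `t_end`).
#' @param seed Root seed; per-run seeds are derived with [derive_seed()].
#' @param ... Extra arguments for the regime simulator (e.g. `method`).
#' @return An object of class `ensemble_summary`: a list with `regime`,
#'   `params`, `noise`, `n_runs`, `mean`, `sd`, `se` (Monte-Carlo
#'   standard error of the mean across runs), `density` (tibble
#'   `bin_left`, `bin_right`, `prob`), `run_means` and `modality`.
#' @export
run_ensemble <- function(regime, params, noise = NULL, ic_sampler = NULL,
                         n_runs = 100, t_end = 1e4,
                         burn_in = 0.2 * t_end, seed = 1, ...) {
  if (n_runs < 1) abort("`n_runs` must be >= 1.")
  if (burn_in >= t_end) abort("`burn_in` must be smaller than `t_end`.")
  sum_w <- sum_x <- sum_x2 <- 0
  hist_counts <- NULL
  run_means <- numeric(n_runs)
  density_tbl <- NULL
  for (i in seq_len(n_runs)) {
    set.seed(derive_seed(seed, i))
    init <- if (is.null(ic_sampler)) NULL else ic_sampler()
    traj <- simulate_motif(regime, params, noise, init = init,
                           t_end = t_end, seed = NULL,
                           burn_in = burn_in, record_dt = t_end, ...)
    st <- trajectory_stats(traj)
    sum_w <- sum_w + st$sum_w
    sum_x <- sum_x + st$sum_x
    sum_x2 <- sum_x2 + st$sum_x2
    counts <- st$density$prob * st$sum_w
    if (is.null(hist_counts)) {
      hist_counts <- counts
      density_tbl <- st$density
    } else {
      hist_counts <- hist_counts + counts
    }
    run_means[i] <- st$mean
  }
  if (sum_w <= 0) abort("no post-burn-in samples were accumulated.")
  density_tbl$prob <- hist_counts / sum(hist_counts)
  mean_hat <- sum_x / sum_w
  sd_hat <- sqrt(max(sum_x2 / sum_w - mean_hat^2, 0))
  se_hat <- if (n_runs > 1) stats::sd(run_means) / sqrt(n_runs) else NA_real_
  out <- list(
    regime = regime, params = params, noise = resolve_noise(noise),
    n_runs = n_runs, t_end = t_end, burn_in = burn_in, seed = seed,
    mean = mean_hat, sd = sd_hat, se = se_hat,
    run_means = run_means, density = density_tbl
  )
  class(out) <- "ensemble_summary"
  out$modality <- classify_modality(out)
  out
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary> regime", x$regime, "|", x$n_runs, "runs |",
      "mean", signif(x$mean, 4), "sd", signif(x$sd, 4),
      "|", x$modality, "\n")
  invisible(x)
}

#' @export
tidy.ensemble_summary <- function(x, ...) {
  x$density
}

#' @export
glance.ensemble_summary <- function(x, ...) {
  tibble::tibble(regime = x$regime, n_runs = x$n_runs, mean = x$mean,
                 sd = x$sd, se = x$se, modality = x$modality)
}

# 3-bin moving-average smoothing of a histogram
smooth3 <- function(p) {
  n <- length(p)
  vapply(seq_len(n), function(i) {
    mean(p[max(1, i - 1):min(n, i + 1)])
  }, numeric(1))
}

# local maxima of the smoothed histogram (optionally above a prominence
# floor expressed as a fraction of the global maximum)
find_modes <- function(prob, min_prom = 0) {
  sm <- smooth3(prob)
  n <- length(sm)
  if (n < 3) return(list(idx = which.max(sm), sm = sm))
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i == 1) -Inf else sm[i - 1]
    right <- if (i == n) -Inf else sm[i + 1]
    sm[i] > left && sm[i] >= right
  }, logical(1))
  idx <- which(is_max & sm >= min_prom * max(sm))
  if (length(idx) == 0) idx <- which.max(sm)
  list(idx = idx, sm = sm)
}

#' Classify the modality of a stationary protein density
#'
#' Kernel-free rule on the histogram: after 3-bin moving-average
#' smoothing, a bin is a mode if it exceeds both neighbours; the density
#' is `bimodal` when two modes exist whose intervening minimum falls
#' below 50% of the smaller mode. A unimodal density is labelled
#' `unimodal_low` or `unimodal_high` by comparing the mode location with
#' the unstable deterministic equilibrium `y_U` (scaled by `omega` for
#' the copy-number regimes).
#'
#' @param summary An `ensemble_summary`, or a density tibble with columns
#'   `bin_left`, `bin_right`, `prob` (then `params` and `regime` must be
#'   given).
#' @param params,regime Needed only when `summary` is a bare density.
#' @param dip_frac Bimodality dip threshold (default 0.5).
#' @param min_prom Mode prominence floor as a fraction of the maximum.
#' @return One of `"unimodal_low"`, `"unimodal_high"`, `"bimodal"`.
#' @export
classify_modality <- function(summary, params = NULL, regime = NULL,
                              dip_frac = 0.5, min_prom = 0) {
  if (inherits(summary, "ensemble_summary")) {
    density <- summary$density
    params <- summary$params
    regime <- summary$regime
  } else {
    density <- summary
    if (is.null(params) || is.null(regime)) {
      abort("`params` and `regime` are required with a bare density.")
    }
  }
  prob <- density$prob
  if (length(prob) == 0 || sum(prob) == 0) abort("empty density.")
  centers <- 0.5 * (density$bin_left + density$bin_right)
  fm <- find_modes(prob, min_prom)
  idx <- fm$idx; sm <- fm$sm
  bimodal <- FALSE
  main <- idx[which.max(sm[idx])]
  second <- NA_integer_
  if (length(idx) >= 2) {
    ord <- idx[order(sm[idx], decreasing = TRUE)]
    for (m in ord[-1]) {
      lo <- min(main, m); hi <- max(main, m)
      dip <- min(sm[lo:hi])
      if (dip < dip_frac * min(sm[main], sm[m])) {
        bimodal <- TRUE; second <- m; break
      }
    }
  }
  if (bimodal) return("bimodal")
  scale <- if (regime %in% c(1L, 2L)) params$omega else 1
  fp <- fixed_points(params)
  y_u <- if (nrow(fp) >= 3) fp$y[fp$stability == "unstable"][1] else {
    # monostable family: split at the midpoint of the attainable range
    0.5 * params$s * params$n / params$d
  }
  if (centers[main] / scale < y_u) "unimodal_low" else "unimodal_high"
}

#' Sweep a phase diagram over noise amplitude and a facet axis
#'
#' Runs one ensemble per cell of a `B` grid crossed with a facet axis
#' (noise autocorrelation `tau`, or volume factor `omega` which rescales
#' the network parameters). Cells are reproducible under the per-cell
#' seed scheme `derive_seed(seed, facet_index * 10^6 + cell_index, run)`.
#'
#' @param regime Integer 1-4.
#' @param params A [network_params()] object.
#' @param noise_kind `"sine_wiener"` or `"cai_lin"`.
#' @param B_grid Ascending grid of noise amplitudes.
#' @param facet Named list of length one: `list(tau = c(1, 10, 100))` or
#'   `list(omega = c(6.022, 60.22, 602.2))`. Use `NULL` for a single-row
#'   sweep at the `tau`/`omega` already implied by `tau`/`params`.
#' @param tau Autocorrelation time used when the facet axis is not `tau`.
#' @param z Cai-Lin shape parameter.
#' @param ic_sampler,n_runs,t_end,burn_in,seed As in [run_ensemble()].
#' @param ... Passed to the regime simulator.
#' @return A tibble of class `phase_diagram` with one row per cell:
#'   `B`, the facet column, `mean`, `sd`, `se`, `modality` and a
#'   list-column `summary` of `ensemble_summary` objects.
#' @export
sweep_phase_diagram <- function(regime, params, noise_kind = "sine_wiener",
                                B_grid, facet = NULL, tau = 10, z = 0.5,
                                ic_sampler = NULL, n_runs = 100,
                                t_end = 1e4, burn_in = 0.2 * t_end,
                                seed = 1, ...) {
  if (length(B_grid) < 1 || is.unsorted(B_grid)) {
    abort("`B_grid` must be an ascending grid of amplitudes.")
  }
  if (is.null(facet)) facet <- list(tau = tau)
  facet_name <- names(facet)
  if (length(facet) != 1L || !facet_name %in% c("tau", "omega")) {
    abort("`facet` must be a single named axis: `tau` or `omega`.")
  }
  facet_vals <- facet[[1L]]
  grid <- tidyr::expand_grid(.facet = facet_vals, B = B_grid)
  rows <- purrr::pmap(
    list(grid$.facet, grid$B, seq_len(nrow(grid))),
    function(fv, b, cell) {
      cell_params <- params
      cell_tau <- tau
      if (facet_name == "omega") {
        cell_params$omega <- fv
      } else {
        cell_tau <- fv
      }
      ns <- noise_spec(noise_kind, B = b, tau = cell_tau, z = z)
      summ <- run_ensemble(regime, cell_params, ns,
                           ic_sampler = ic_sampler, n_runs = n_runs,
                           t_end = t_end, burn_in = burn_in,
                           seed = derive_seed(seed, cell), ...)
      tibble::tibble(!!facet_name := fv, B = b, mean = summ$mean,
                     sd = summ$sd, se = summ$se,
                     modality = summ$modality, summary = list(summ))
    })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phase_diagram", class(out))
  attr(out, "regime") <- regime
  attr(out, "params") <- params
  attr(out, "facet") <- facet_name
  attr(out, "seed") <- seed
  out
}

#' Detect a first-order (discontinuous) transition along a mean-vs-B row
#'
#' Locates the largest jump of the long-run mean between adjacent noise
#' amplitudes and reports a transition at the midpoint when the jump
#' exceeds both an absolute threshold and 5 times the local Monte-Carlo
#' error, and (when `classes` is given) separates the low and high mean
#' classes. The divergent-variance signature (`sd` at the transition
#' exceeding both neighbours) is reported alongside.
#'
#' @param row A tibble with columns `B`, `mean`, `se` and optionally `sd`
#'   (e.g. one facet of a [sweep_phase_diagram()] result), at least 5
#'   rows.
#' @param abs_threshold Minimum absolute jump of the mean (default 1, in
#'   `y` units).
#' @param mc_factor Multiple of the local Monte-Carlo error the jump must
#'   exceed.
#' @param classes Optional `c(low, high)`: the means must be `< low`
#'   below the jump and `> high` above it.
#' @return A one-row tibble with `B_transition`, `jump`, `sigma_peak`, or
#'   `NULL` when no jump qualifies.
#' @export
detect_first_order <- function(row, abs_threshold = 1, mc_factor = 5,
                               classes = c(1, 3)) {
  if (nrow(row) < 5) abort("need at least 5 grid points.")
  row <- dplyr::arrange(row, .data$B)
  m <- row$mean
  if (!is.null(classes)) {
    # boundary between the low-mean and high-mean classes; cells inside
    # the jump region may hold mixtures of escaped and trapped runs
    low <- which(m < classes[1])
    high <- which(m > classes[2])
    if (length(low) == 0 || length(high) == 0) return(NULL)
    increasing <- max(low) < min(high)
    decreasing <- max(high) < min(low)
    if (!increasing && !decreasing) return(NULL)
    i0 <- if (increasing) max(low) else max(high)
    i1 <- if (increasing) min(high) else min(low)
  } else {
    i0 <- which.max(abs(diff(m)))
    i1 <- i0 + 1L
  }
  jump <- m[i1] - m[i0]
  se_loc <- if (!is.null(row$se) && all(is.finite(row$se[c(i0, i1)]))) {
    sqrt(row$se[i0]^2 + row$se[i1]^2)
  } else 0
  if (abs(jump) <= abs_threshold || abs(jump) <= mc_factor * se_loc) {
    return(NULL)
  }
  sigma_peak <- if (!is.null(row$sd)) {
    s <- row$sd
    j <- (i0:i1)[which.max(s[i0:i1])]
    nb <- c(if (i0 > 1) s[i0 - 1], if (i1 < length(s)) s[i1 + 1])
    length(nb) == 0 || all(s[j] >= nb)
  } else NA
  tibble::tibble(
    B_transition = 0.5 * (row$B[i0] + row$B[i1]),
    jump = jump, sigma_peak = sigma_peak
  )
}

#' Detect a second-order transition (bimodality onset) along a B row
#'
#' Reports the smallest noise amplitude at which the pooled stationary
#' density is classified bimodal by the two-mode rule of
#' [classify_modality()], cross-checked against growth of the standard
#' deviation at the onset.
#'
#' @param row A facet of a [sweep_phase_diagram()] result: tibble with
#'   `B`, `modality`, `sd`.
#' @return A one-row tibble with `B_onset` and `sd_growing`, or `NULL`
#'   when no cell is bimodal.
#' @export
detect_second_order <- function(row) {
  if (nrow(row) < 2) abort("need at least 2 grid points.")
  row <- dplyr::arrange(row, .data$B)
  i <- which(row$modality == "bimodal")[1]
  if (is.na(i)) return(NULL)
  sd_growing <- if (i > 1) row$sd[i] > row$sd[i - 1] else NA
  tibble::tibble(B_onset = row$B[i], sd_growing = sd_growing)
}

#' Classify every cell of a phase diagram and list detected transitions
#'
#' Convenience wrapper running [detect_first_order()] and
#' [detect_second_order()] per facet of a phase diagram.
#'
#' @param diagram A `phase_diagram`.
#' @param ... Passed to [detect_first_order()].
#' @return A tibble with one row per facet and transition kind.
#' @export
detect_transitions <- function(diagram, ...) {
  facet_name <- attr(diagram, "facet")
  groups <- dplyr::group_split(dplyr::group_by(
    diagram, !!rlang::sym(facet_name)))
  purrr::map_dfr(groups, function(g) {
    fv <- g[[facet_name]][1]
    fo <- tryCatch(detect_first_order(g, ...), error = function(e) NULL)
    so <- tryCatch(detect_second_order(g), error = function(e) NULL)
    dplyr::bind_rows(
      if (!is.null(fo)) {
        tibble::tibble(!!facet_name := fv, kind = "first_order",
                       B = fo$B_transition)
      },
      if (!is.null(so)) {
        tibble::tibble(!!facet_name := fv, kind = "second_order",
                       B = so$B_onset)
      }
    )
  })
}

#' @export
tidy.phase_diagram <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$summary <- NULL
  out
}

#' @export
glance.phase_diagram <- function(x, ...) {
  tibble::tibble(
    regime = attr(x, "regime"),
    facet = attr(x, "facet"),
    n_cells = nrow(x),
    n_bimodal = sum(x$modality == "bimodal")
  )
}

#' Export a phase diagram as long-format CSV
#'
#' Columns `regime`, `B`, `tau`, `omega`, `mean`, `sd`, `modality`.
#' @param diagram A `phase_diagram`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_phase_diagram_csv <- function(diagram, file) {
  facet_name <- attr(diagram, "facet")
  params <- attr(diagram, "params")
  out <- tibble::as_tibble(diagram)
  out$summary <- NULL
  out$regime <- attr(diagram, "regime")
  if (!"tau" %in% names(out)) {
    out$tau <- purrr::map_dbl(diagram$summary, ~ .x$noise$tau)
  }
  if (!"omega" %in% names(out)) out$omega <- params$omega
  readr::write_csv(
    out[, c("regime", "B", "tau", "omega", "mean", "sd", "modality")],
    file)
  invisible(file)
}

#' Export a stationary density as CSV
#'
#' Columns `bin_left`, `bin_right`, `prob`.
#' @param summary An `ensemble_summary` (or bare density tibble).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_density_csv <- function(summary, file) {
  density <- if (inherits(summary, "ensemble_summary")) {
    summary$density
  } else summary
  readr::write_csv(density, file)
  invisible(file)
}
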