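#' Fixed points of the noise-free fast-switching mean-field model
#'
#' In the fast-switching, many-protein limit the protein density obeys
#' `dy/dt = s n c(y) / (c(y) + b0) - d y` with `c(y) = c0 + c2 y^2`.
#' Dividing through by `c0`, the steady states depend on the rates only
#' through the ratios `c2/c0` and `b0/c0`. This function finds all
#' nonnegative roots of the steady-state equation by sign-change
#' bracketing on a dense grid over `[0, s n / d + 1]` followed by
#' bisection, polishing each root to `|residual| < 1e-10`. Stability is
#' read off the sign of the derivative of the right-hand side at the root.
#'
#' @param params A [network_params()] object (supplies `s`, `n`, `d` and
#'   the ratio `c2/c0`).
#' @param b0_over_c0 Ratio of deactivation to baseline activation rate;
#'   defaults to the value implied by `params`.
#' @param grid_n Number of bracketing grid points.
#' @return A tibble of class `fixed_point_set` with columns `y`
#'   (ascending) and `stability` (`"stable"`/`"unstable"`), plus the
#'   ratio as attribute `b0_over_c0`.
#' @examples
#' fixed_points(network_params())   # y = 0.6268, 1.489, 4.28
#' @export
fixed_points <- function(params, b0_over_c0 = params$b0 / params$c0,
                         grid_n = 1e4) {
  s <- params$s; n <- params$n; d <- params$d
  r2 <- params$c2 / params$c0          # c2/c0
  rhs <- function(y) {
    cy <- 1 + r2 * y^2                 # c(y)/c0
    s * n * cy / (cy + b0_over_c0) - d * y
  }
  upper <- s * n / d + 1
  yg <- seq(0, upper, length.out = grid_n)
  fg <- rhs(yg)
  roots <- yg[fg == 0]
  idx <- which(fg[-length(fg)] * fg[-1] < 0)
  for (i in idx) {
    lo <- yg[i]; hi <- yg[i + 1]
    flo <- rhs(lo)
    for (k in 1:200) {
      mid <- 0.5 * (lo + hi)
      fmid <- rhs(mid)
      if (flo * fmid <= 0) hi <- mid else { lo <- mid; flo <- fmid }
      if (abs(fmid) < 1e-12 || (hi - lo) < 1e-14) break
    }
    roots <- c(roots, 0.5 * (lo + hi))
  }
  roots <- sort(roots)
  # merge numerically coalescing roots (saddle-node degeneracy)
  if (length(roots) > 1) {
    roots <- roots[c(TRUE, diff(roots) > 1e-6)]
  }
  eps <- 1e-7
  stab <- vapply(roots, function(r) {
    lo <- max(r - eps, 0)
    slope <- (rhs(r + eps) - rhs(lo)) / (r + eps - lo)
    if (slope < 0) "stable" else "unstable"
  }, character(1))
  out <- tibble::tibble(y = roots, stability = stab)
  class(out) <- c("fixed_point_set", class(out))
  attr(out, "b0_over_c0") <- b0_over_c0
  attr(out, "params") <- params
  out
}

#' Hysteresis (bifurcation) diagram in the deactivation rate
#'
#' Sweeps the ratio `b0/c0` and records the steady states of the
#' noise-free fast-switching model at each value, then locates the
#' bistability interval (the two saddle-node folds, where the root count
#' changes between 1 and 3) by bisection on the root count to relative
#' precision `1e-6`.
#'
#' @param params A [network_params()] object.
#' @param b0_over_c0 Ascending grid of ratios, length `>= 3`.
#' @return A tibble of class `bifurcation_diagram` with columns
#'   `b0_over_c0`, `y`, `stability`; the bistability interval (or `NULL`)
#'   is in attribute `bistable_interval`.
#' @examples
#' hysteresis_scan(network_params(), seq(5, 30, by = 0.5))
#' @export
hysteresis_scan <- function(params, b0_over_c0) {
  if (length(b0_over_c0) < 3 || is.unsorted(b0_over_c0, strictly = TRUE)) {
    abort("`b0_over_c0` must be a strictly ascending grid of length >= 3.")
  }
  rows <- purrr::map(b0_over_c0, function(r) {
    fp <- fixed_points(params, b0_over_c0 = r)
    tibble::tibble(b0_over_c0 = r, y = fp$y, stability = fp$stability)
  })
  out <- dplyr::bind_rows(rows)
  n_roots <- function(r) nrow(fixed_points(params, b0_over_c0 = r))
  counts <- vapply(b0_over_c0, n_roots, numeric(1))
  interval <- NULL
  if (any(counts >= 3)) {
    bi <- range(b0_over_c0[counts >= 3])
    refine <- function(lo, hi, want_hi_multi) {
      # bisect a fold bracketed between a 1-root and a 3-root ratio
      for (k in 1:100) {
        mid <- 0.5 * (lo + hi)
        multi <- n_roots(mid) >= 3
        if (multi == want_hi_multi) hi <- mid else lo <- mid
        if ((hi - lo) / max(hi, 1) < 1e-6) break
      }
      0.5 * (lo + hi)
    }
    i_lo <- match(bi[1], b0_over_c0)
    i_hi <- match(bi[2], b0_over_c0)
    left <- if (i_lo > 1) {
      refine(b0_over_c0[i_lo - 1], bi[1], want_hi_multi = TRUE)
    } else bi[1]
    right <- if (i_hi < length(b0_over_c0)) {
      refine(bi[2], b0_over_c0[i_hi + 1], want_hi_multi = FALSE)
    } else bi[2]
    interval <- c(lower = left, upper = right)
  }
  class(out) <- c("bifurcation_diagram", class(out))
  attr(out, "bistable_interval") <- interval
  attr(out, "params") <- params
  out
}

#' Export a bifurcation diagram as CSV
#'
#' Columns `b0_over_c0`, `y`, `stability`.
#' @param diagram A `bifurcation_diagram`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_bifurcation_csv <- function(diagram, file) {
  readr::write_csv(tibble::as_tibble(diagram), file)
  invisible(file)
}

#' @export
tidy.fixed_point_set <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.fixed_point_set <- function(x, ...) {
  tibble::tibble(
    n_roots = nrow(x),
    bistable = nrow(x) == 3L,
    b0_over_c0 = attr(x, "b0_over_c0")
  )
}

#' @export
tidy.bifurcation_diagram <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.bifurcation_diagram <- function(x, ...) {
  iv <- attr(x, "bistable_interval")
  tibble::tibble(
    bistable = !is.null(iv),
    fold_lower = if (is.null(iv)) NA_real_ else iv[["lower"]],
    fold_upper = if (is.null(iv)) NA_real_ else iv[["upper"]]
  )
}
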