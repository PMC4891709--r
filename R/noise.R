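#' Specify a bounded extrinsic noise process
#'
#' The gene deactivation rate is perturbed multiplicatively,
#' `b0(t) = b0 * (1 + xi(t))`, by a bounded stochastic process `xi(t)`
#' confined to `[-B, B]` with mean zero, so the perturbed rate is never
#' negative and its long-run average stays at the baseline `b0`. Two
#' families are supported:
#'
#' * `"sine_wiener"`: `xi(t) = B * sin(sqrt(2 / tau) * W(t))` with `W` a
#'   standard Wiener process. Its stationary density is the horn-shaped
#'   arcsine law on `(-B, B)`.
#' * `"cai_lin"`: the bounded diffusion
#'   `dxi = -(xi / tau) dt + sqrt((B^2 - xi^2) / (tau (1 + z))) dW`,
#'   whose stationary density is proportional to `(1 - xi^2 / B^2)^z`:
#'   bell-shaped for `z > 0`, horn-shaped for `-1 < z < 0`.
#'
#' @param kind `"sine_wiener"` or `"cai_lin"`.
#' @param B Noise amplitude in `[0, 1]`; `xi` is confined to `[-B, B]`.
#' @param tau Autocorrelation time (dimensionless, in units of the protein
#'   degradation time); must be positive.
#' @param z Shape parameter of the Cai-Lin stationary density; must exceed
#'   -1. Ignored for sine-Wiener noise.
#'
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec("sine_wiener", B = 0.1, tau = 10)
#' noise_spec("cai_lin", B = 0.9, tau = 10, z = -0.5)
#' @export
noise_spec <- function(kind = c("sine_wiener", "cai_lin"), B, tau = 1,
                       z = 0.5) {
  kind <- match.arg(kind)
  if (!is.numeric(B) || length(B) != 1L || is.na(B) || B < 0 || B > 1) {
    abort("`B` must be a single number in [0, 1].")
  }
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    abort("`tau` must be a single positive number.")
  }
  if (kind == "cai_lin" &&
      (!is.numeric(z) || length(z) != 1L || is.na(z) || z <= -1)) {
    abort("`z` must be a single number > -1 for Cai-Lin noise.")
  }
  structure(
    list(kind = kind, B = as.numeric(B), tau = as.numeric(tau),
         z = if (kind == "cai_lin") as.numeric(z) else NA_real_),
    class = "noise_spec"
  )
}

#' @export
print.noise_spec <- function(x, ...) {
  cat("<noise_spec> ", x$kind, ": B = ", x$B, ", tau = ", x$tau,
      if (x$kind == "cai_lin") paste0(", z = ", x$z), "\n", sep = "")
  invisible(x)
}

#' Default noise integration step
#'
#' Resolves both the noise correlation time and the unit protein
#' degradation time: `min(tau, 1) / 100`.
#' @param spec A [noise_spec()].
#' @return A single positive step size.
#' @export
noise_dt <- function(spec) {
  min(spec$tau, 1) / 100
}

#' Draw one value from the stationary law of a bounded noise
#'
#' For sine-Wiener the construction forces `xi(0) = 0` (since `W(0) = 0`),
#' so this is only used for Cai-Lin paths, which start from their
#' stationary density so long-run statistics carry no initialisation
#' transient. The Cai-Lin stationary density `p(xi) \eqn{\propto}
#' (1 - xi^2/B^2)^z` maps to `(xi/B)^2 ~ Beta(1/2, z + 1)` with a random
#' sign.
#'
#' @param spec A [noise_spec()].
#' @return A single value in `[-B, B]`.
#' @keywords internal
noise_stationary_draw <- function(spec) {
  if (spec$B == 0) return(0)
  if (spec$kind == "sine_wiener") return(0)
  w <- rbeta(1L, 0.5, spec$z + 1)
  sgn <- if (runif(1L) < 0.5) -1 else 1
  spec$B * sgn * sqrt(w)
}

#' Stationary cumulative distribution of a bounded noise
#'
#' Closed forms used as oracles: the arcsine law for sine-Wiener,
#' `F(x) = 1/2 + asin(x / B) / pi`, and for Cai-Lin the Beta
#' representation `F(x) = (1 + sign(x) * pbeta((x/B)^2, 1/2, z+1)) / 2`.
#'
#' @param q Quantiles (clamped to `[-B, B]`).
#' @param spec A [noise_spec()].
#' @return Probabilities.
#' @export
noise_stationary_cdf <- function(q, spec) {
  x <- pmin(pmax(q / spec$B, -1), 1)
  if (spec$kind == "sine_wiener") {
    0.5 + asin(x) / pi
  } else {
    0.5 * (1 + sign(x) * pbeta(x^2, 0.5, spec$z + 1))
  }
}

#' Sample one bounded-noise path on a uniform time grid
#'
#' Paths are deterministic given the RNG state: call `set.seed()` (or pass
#' `seed`) for reproducibility. When `B = 0` the path is identically zero
#' and no random numbers are consumed, so a zero-amplitude run is
#' bit-identical to a noise-free run with the same seed.
#'
#' @param spec A [noise_spec()].
#' @param t_end End of the time grid (the grid starts at 0).
#' @param dt Grid step; defaults to [noise_dt()].
#' @param seed Optional integer seed set before sampling.
#' @return A tibble with columns `time` and `xi`, of class `noise_path`.
#' @examples
#' sample_noise(noise_spec("sine_wiener", B = 0.5, tau = 1), t_end = 10,
#'              seed = 1)
#' @export
sample_noise <- function(spec, t_end, dt = noise_dt(spec), seed = NULL) {
  stopifnot(inherits(spec, "noise_spec"))
  if (!is.numeric(t_end) || t_end <= 0) abort("`t_end` must be positive.")
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be positive.")
  if (!is.null(seed)) set.seed(seed)
  n_steps <- ceiling(t_end / dt)
  times <- seq(0, by = dt, length.out = n_steps + 1)
  xi <- sample_noise_values(spec, n_steps, dt)
  out <- tibble::tibble(time = times, xi = xi)
  class(out) <- c("noise_path", class(out))
  attr(out, "spec") <- spec
  out
}

# bare numeric path; consumes the RNG stream only when B > 0
sample_noise_values <- function(spec, n_steps, dt) {
  if (spec$B == 0) return(rep(0, n_steps + 1))
  if (spec$kind == "sine_wiener") {
    w <- cumsum(c(0, rnorm(n_steps, sd = sqrt(dt))))
    spec$B * sin(sqrt(2 / spec$tau) * w)
  } else {
    xi0 <- noise_stationary_draw(spec)
    cpp_cai_lin_path(spec$B, spec$tau, spec$z, dt, n_steps, xi0)
  }
}

#' Ensemble statistics of bounded-noise paths
#'
#' Pools a collection of noise paths and reports the ensemble mean, an
#' empirical autocovariance estimate (computed on the first path over the
#' requested lags) and a histogram of pooled values. The histogram support
#' is contained in `[-B, B]` by construction.
#'
#' @param paths A list of `noise_path` tibbles (or a single one).
#' @param lags Integer lags (in grid steps) for the autocovariance.
#' @param bins Number of histogram bins over `[-B, B]`.
#' @return A list with `mean`, `autocovariance` (tibble `lag`, `acov`) and
#'   `histogram` (tibble `bin_left`, `bin_right`, `prob`).
#' @export
empirical_noise_stats <- function(paths, lags = 0:50, bins = 50) {
  if (inherits(paths, "noise_path")) paths <- list(paths)
  if (length(paths) == 0L) abort("`paths` must contain at least one path.")
  spec <- attr(paths[[1L]], "spec")
  values <- unlist(purrr::map(paths, "xi"))
  x1 <- paths[[1L]]$xi
  n <- length(x1)
  acov <- purrr::map_dbl(lags, function(l) {
    if (l >= n) return(NA_real_)
    mean((x1[seq_len(n - l)] - mean(x1)) * (x1[seq_len(n - l) + l] - mean(x1)))
  })
  B <- if (!is.null(spec) && spec$B > 0) spec$B else max(abs(values), 1e-12)
  edges <- seq(-B, B, length.out = bins + 1)
  counts <- graphics::hist(pmin(pmax(values, -B), B), breaks = edges,
                           plot = FALSE)$counts
  list(
    mean = mean(values),
    autocovariance = tibble::tibble(lag = lags, acov = acov),
    histogram = tibble::tibble(bin_left = edges[-(bins + 1)],
                               bin_right = edges[-1],
                               prob = counts / sum(counts))
  )
}

#' Write a noise path to CSV
#'
#' Two columns, `time` and `xi`, with a header line.
#' @param path A `noise_path` tibble.
#' @param file Output file path.
#' @return `file`, invisibly.
#' @export
write_noise_csv <- function(path, file) {
  readr::write_csv(tibble::as_tibble(path)[, c("time", "xi")], file)
  invisible(file)
}
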