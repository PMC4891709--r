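#' Kinetic parameters of the self-activating motif
#'
#' The motif is a gene with `n` copies whose product, a transcription
#' factor, feeds back positively on its own activation rate,
#' `c(y) = c0 + c2 * y^2`. Time is nondimensionalised by the protein
#' degradation time, so `d = 1`. The gene-switching rates carry a common
#' scale factor `h`: `(c0, c2, b0) = h * (c0_base, 1.6 * c0_base,
#' 15 * c0_base)`, with `h = 1` modelling slow switching and `h >> 1` fast
#' switching. The volume factor `omega = N_A * V` converts protein
#' concentration `y` to copy number `Y = omega * y`.
#'
#' Defaults reproduce the reference parametrisation: `c0_base = 10`,
#' `b0 = 15 * c0`, `c2 = 1.6 * c0`, `s = 3.2`, `n = 2`.
#'
#' @param h Switching-scale parameter, `>= 1`.
#' @param c0_base Baseline activation rate at `h = 1`.
#' @param n Gene copy number (diploid default 2).
#' @param s Protein synthesis rate per active gene.
#' @param d Protein degradation rate (1 after nondimensionalisation).
#' @param omega Volume factor `N_A * V` (proteins per unit concentration).
#'   The default 6.022 corresponds to a 10 um^3 bacterium-like volume;
#'   60.22 and 602.2 scale it to 100 and 1000 um^3.
#' @param c0,c2,b0 Override the scaled rates directly (rarely needed; by
#'   default they are derived from `h` and `c0_base`).
#' @return An object of class `network_params`.
#' @examples
#' network_params()                 # slow switching, h = 1
#' network_params(h = 100)          # operational stand-in for h >> 1
#' @export
network_params <- function(h = 1, c0_base = 10, n = 2, s = 3.2, d = 1,
                           omega = 6.022,
                           c0 = h * c0_base, c2 = 1.6 * h * c0_base,
                           b0 = 15 * h * c0_base) {
  vals <- c(h = h, c0_base = c0_base, n = n, s = s, d = d, omega = omega,
            c0 = c0, c2 = c2, b0 = b0)
  if (any(!is.finite(vals))) abort("all parameters must be finite numbers.")
  if (any(c(s, d, c0, c2, b0) < 0)) abort("rates must be nonnegative.")
  if (h < 1) abort("`h` must be >= 1.")
  if (omega <= 0) abort("`omega` must be positive.")
  if (n < 1 || n != round(n)) abort("`n` must be a positive integer.")
  structure(
    list(n = as.integer(n), s = s, d = d, c0 = c0, c2 = c2, b0 = b0,
         h = h, c0_base = c0_base, omega = omega),
    class = "network_params"
  )
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params> n =", x$n, " s =", x$s, " d =", x$d,
      "\n  c0 =", x$c0, " c2 =", x$c2, " b0 =", x$b0,
      " (h =", x$h, ")\n  omega =", x$omega, "\n")
  invisible(x)
}

#' Convert Smolen-Baxter-Byrne rate constants
#'
#' Maps the dimensional constants of the reference deterministic model
#' (degradation `d` in 1/min, basal transcription `R_b` in 1/min,
#' feedback dissociation `K_d` in nM^2, maximal feedback transcription
#' `K_f` in 1/min) to the nondimensional motif parameters with time unit
#' `1/d`: `n * s = R_b + K_f` and `b0 = c0 * K_f / R_b`. The feedback
#' coefficient is `c2 = 1.6 * c0` in these units. At the default constants
#' this gives `s = 3.2` and `b0 = 15 * c0`.
#'
#' @param d,R_b,K_d,K_f Dimensional constants (defaults: 1, 0.4, 10, 6).
#' @param n Gene copy number.
#' @param c0_base Baseline activation rate at `h = 1`.
#' @param h Switching-scale parameter.
#' @param omega Volume factor.
#' @return A [network_params()] object.
#' @examples
#' convert_sbb_parameters()          # s = 3.2, b0/c0 = 15
#' convert_sbb_parameters(n = 1)     # haploid: s = 6.4
#' @export
convert_sbb_parameters <- function(d = 1, R_b = 0.4, K_d = 10, K_f = 6,
                                   n = 2, c0_base = 10, h = 1,
                                   omega = 6.022) {
  if (any(c(d, R_b, K_d, K_f) <= 0)) {
    abort("all Smolen-Baxter-Byrne constants must be positive.")
  }
  s <- (R_b + K_f) / n / d          # per-copy synthesis, time unit 1/d
  b0_over_c0 <- K_f / R_b
  network_params(h = h, c0_base = c0_base, n = n, s = s, d = 1,
                 omega = omega,
                 b0 = b0_over_c0 * h * c0_base)
}

#' Gene activation rate with positive feedback
#'
#' `c(y) = c0 + c2 * y^2`, evaluated at protein concentration `y`.
#' @param y Protein concentration(s), `>= 0`.
#' @param params A [network_params()] object.
#' @return Rate(s), same length as `y`.
#' @export
activation_rate <- function(y, params) {
  if (any(y < 0)) abort("`y` must be nonnegative.")
  params$c0 + params$c2 * y^2
}

#' Perturbed gene deactivation rate
#'
#' `b0(t) = b0 * (1 + xi)`, nonnegative because `|xi| <= 1`.
#' @param params A [network_params()] object.
#' @param xi Noise value(s) with `|xi| <= 1`.
#' @return Rate(s).
#' @export
deactivation_rate <- function(params, xi) {
  if (any(abs(xi) > 1)) abort("`xi` must lie in [-1, 1].")
  params$b0 * (1 + xi)
}

#' Jump propensities of the exact discrete model
#'
#' For state `(G, Y)` with `G` active gene copies and `Y` protein copies:
#' `a1 = b0(t) G` (deactivation), `a2 = c0 (n - G)` (basal activation),
#' `a3 = c2 Y^2 (n - G) / omega^2` (feedback activation),
#' `a4 = s omega G` (transcription), `a5 = d Y` (degradation).
#'
#' @param G Active gene count in `0..n`.
#' @param Y Protein copy number, `>= 0`.
#' @param params A [network_params()] object.
#' @param xi Current noise value, `|xi| <= 1`.
#' @return Named numeric vector `c(a1, a2, a3, a4, a5)`.
#' @examples
#' propensities(G = 1, Y = 10, network_params(), xi = 0)
#' @export
propensities <- function(G, Y, params, xi = 0) {
  if (G < 0 || G > params$n || G != round(G)) {
    abort("`G` must be an integer in 0..n.")
  }
  if (Y < 0) abort("`Y` must be nonnegative.")
  c(a1 = deactivation_rate(params, xi) * G,
    a2 = params$c0 * (params$n - G),
    a3 = params$c2 * Y^2 * (params$n - G) / params$omega^2,
    a4 = params$s * params$omega * G,
    a5 = params$d * Y)
}
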