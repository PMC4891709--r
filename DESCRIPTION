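Package: bnmotif
Title: Bounded-Noise Perturbation of a Self-Activating Gene Motif
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale stochastic simulation of the positive-feedback
    transcriptional motif (a transcription factor activating its own gene)
    whose gene deactivation rate is perturbed by bounded extrinsic noise
    (sine-Wiener or Cai-Lin). Implements four model regimes spanning
    slow/fast gene switching and few/many protein copies: an exact
    time-inhomogeneous Gillespie algorithm, hybrid birth-death and
    piecewise-deterministic Markov process samplers, and a mean-field
    ordinary differential equation. Provides deterministic fixed-point and
    hysteresis analysis, ensemble estimation of stationary protein
    densities, and detection of noise-induced first- and second-order
    transitions over noise-amplitude, autocorrelation-time and cell-volume
    grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
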