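#' @import ggplot2
NULL

#' Plot a simulated trajectory
#'
#' Protein level (and noise, as a second panel variable) against time.
#' @param object A `motif_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motif_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(df[, c("time", "protein", "xi")],
                              -"time", names_to = "series")
  ggplot(long, aes(x = .data$time, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~.data$series, ncol = 1, scales = "free_y") +
    labs(x = "time (units of 1/d)", y = NULL) +
    theme_minimal()
}

#' Plot a stationary protein density
#'
#' @param object An `ensemble_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ensemble_summary <- function(object, ...) {
  d <- object$density
  d$center <- 0.5 * (d$bin_left + d$bin_right)
  ggplot(d, aes(x = .data$center, y = .data$prob)) +
    geom_col(width = d$bin_right[1] - d$bin_left[1], fill = "steelblue") +
    labs(x = if (object$regime %in% c(1, 2)) "protein count Y"
             else "protein density y",
         y = "stationary probability",
         subtitle = paste0("regime ", object$regime, ", ",
                           object$modality)) +
    theme_minimal()
}

#' Plot a phase diagram
#'
#' Long-run mean with a +/- sd ribbon against noise amplitude, faceted
#' by the sweep's facet axis; points are coloured by modality.
#' @param object A `phase_diagram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phase_diagram <- function(object, ...) {
  facet_name <- attr(object, "facet")
  df <- tibble::as_tibble(object)
  df$summary <- NULL
  ggplot(df, aes(x = .data$B, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd,
                    ymax = .data$mean + .data$sd), alpha = 0.2) +
    geom_line() +
    geom_point(aes(colour = .data$modality)) +
    facet_wrap(stats::as.formula(paste("~", facet_name)),
               labeller = label_both) +
    labs(x = "noise amplitude B", y = "long-run protein mean") +
    theme_minimal()
}

#' Plot a hysteresis (bifurcation) diagram
#'
#' Stable branches drawn solid, the unstable branch dashed; the
#' bistability interval, when present, is shaded.
#' @param object A `bifurcation_diagram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bifurcation_diagram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  iv <- attr(object, "bistable_interval")
  p <- ggplot(df, aes(x = .data$b0_over_c0, y = .data$y,
                      linetype = .data$stability,
                      group = .data$stability)) +
    geom_point(size = 0.5) +
    labs(x = "b0 / c0", y = "equilibrium protein density y") +
    theme_minimal()
  if (!is.null(iv)) {
    p <- p + annotate("rect", xmin = iv[["lower"]], xmax = iv[["upper"]],
                      ymin = -Inf, ymax = Inf, alpha = 0.1,
                      fill = "orange")
  }
  p
}

#' Plot bounded-noise diagnostics
#'
#' Empirical histogram of pooled noise values overlaid with the
#' closed-form stationary density of the process.
#' @param stats Output of [empirical_noise_stats()].
#' @param spec The [noise_spec()] the paths were drawn from.
#' @return A ggplot.
#' @export
plot_noise_density <- function(stats, spec) {
  h <- stats$histogram
  h$center <- 0.5 * (h$bin_left + h$bin_right)
  width <- h$bin_right[1] - h$bin_left[1]
  h$theory <- (noise_stationary_cdf(h$bin_right, spec) -
                 noise_stationary_cdf(h$bin_left, spec))
  ggplot(h, aes(x = .data$center)) +
    geom_col(aes(y = .data$prob), width = width, fill = "grey70") +
    geom_line(aes(y = .data$theory), colour = "firebrick") +
    labs(x = "xi", y = "probability per bin") +
    theme_minimal()
}
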