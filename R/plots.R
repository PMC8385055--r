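#' Plot observed vs Poisson-predicted droplet occupancy
#'
#' Bar diagram of the observed fraction of droplets per occupancy class
#' with the independent-Poisson prediction overlaid as points.
#'
#' @param comparison Output of [compare_observed_predicted()].
#' @param min_frac Hide classes below this observed and predicted fraction.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(comparison, min_frac = 1e-3) {
  df <- comparison[comparison$observed_frac >= min_frac |
                   comparison$predicted_frac >= min_frac, ]
  df$class <- factor(df$class, levels = df$class[order(-df$predicted_frac)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed_frac), fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$predicted_frac), colour = "red") +
    ggplot2::labs(x = "occupancy class (E:T)", y = "fraction of droplets",
                  title = "Observed (bars) vs Poisson-predicted (points) occupancy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-hour lytic-hit kinetics
#'
#' @param x A `droplet_kinetics` or `kinetics_summary` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.droplet_kinetics <- function(x, ...) {
  autoplot.kinetics_summary(x$kinetics, ...)
}

#' @rdname autoplot.droplet_kinetics
#' @export
autoplot.kinetics_summary <- function(x, ...) {
  ggplot2::ggplot(x$histogram, ggplot2::aes(x = .data$hour, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = x$t_fast + 0.5, linetype = "dashed") +
    ggplot2::labs(x = "death time (h)", y = "lytic hits",
                  title = sprintf("Lytic-hit kinetics (fast killers ≤ %g h: %s)",
                                  x$t_fast,
                                  if (is.na(x$fast_killer_fraction)) "NA"
                                  else sprintf("%.0f%%", 100 * x$fast_killer_fraction))) +
    ggplot2::theme_minimal()
}

#' Plot per-droplet viability traces
#'
#' Background-corrected viability intensity over time, one line per
#' droplet; the death-call threshold is drawn as a dashed line. Mirrors the
#' alive = 0 convention: live cells sit on the baseline, dead cells step up
#' and stay up.
#'
#' @param traces Trace tibble ([analyze_cells()] or [simulate_cohort()]).
#' @param cell_type Which traces to show (default target).
#' @param theta Optional threshold to draw.
#' @return A ggplot object.
#' @export
plot_viability_traces <- function(traces, cell_type = "target", theta = NULL) {
  df <- traces[traces$cell_type == cell_type, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$intensity,
                                        group = .data$track_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "time (h)", y = "viability intensity (corrected)",
                  title = sprintf("%s viability traces", cell_type)) +
    ggplot2::theme_minimal()
  if (!is.null(theta)) p <- p + ggplot2::geom_hline(yintercept = theta,
                                                    linetype = "dashed")
  p
}
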