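# ggplot2 helpers for the package's result objects.

#' Plot a torque-angle work loop
#'
#' Draws the (angle, torque) trajectory of a gait cycle; the subtitle
#' reports loop direction and area (counterclockwise = net positive work).
#'
#' @param cycle A `bg_gait_cycle`.
#' @return A ggplot object.
#' @export
plot_torque_angle <- function(cycle) {
  stopifnot(inherits(cycle, "bg_gait_cycle"))
  loop <- torque_angle_loop(cycle)
  ggplot2::ggplot(cycle, ggplot2::aes(x = .data$angle, y = .data$torque)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$pct)) +
    ggplot2::scale_colour_viridis_c(name = "% cycle") +
    ggplot2::labs(
      x = "ankle angle (deg, DF positive)", y = "torque (Nm/kg)",
      title = "Torque-angle work loop",
      subtitle = sprintf("%s, area %.3f J/kg", loop$direction, loop$area)) +
    ggplot2::theme_minimal()
}

#' Plot gait-cycle traces
#'
#' Angle, torque and power of a normalized cycle against percent cycle,
#' with the stance/swing boundary marked.
#'
#' @param cycle A `bg_gait_cycle`.
#' @return A ggplot object.
#' @export
plot_gait_cycle <- function(cycle) {
  stopifnot(inherits(cycle, "bg_gait_cycle"))
  long <- tidyr::pivot_longer(cycle, c("angle", "torque", "power"),
                              names_to = "signal")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pct, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(cycle, "stance_end_pct"),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "% gait cycle", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cohort metric against the afferent statistic
#'
#' Scatter with the least-squares line; the subtitle reports `r`, its 95 %
#' confidence interval and the slope.
#'
#' @param cohort Data frame with `afferent`, the metric column and `group`.
#' @param metric Metric column name (string).
#' @return A ggplot object.
#' @export
plot_afferent_correlation <- function(cohort, metric) {
  stopifnot(metric %in% names(cohort), "afferent" %in% names(cohort))
  res <- pearson_with_ci(cohort, afferent, !!rlang::sym(metric))
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$afferent,
                                       y = .data[[metric]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::labs(
      x = "agonist-antagonist afferent (Imp/s)", y = metric,
      subtitle = sprintf("r = %.2f [%.2f, %.2f], m = %.3g",
                         res$r, res$ci_lo, res$ci_hi, res$slope)) +
    ggplot2::theme_minimal()
}

#' Autoplot a composite-score PCA
#'
#' PC1 scores by subject (coloured by group when present).
#'
#' @param object A `bg_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bg_pca <- function(object, ...) {
  sc <- object$scores
  sc$idx <- seq_len(nrow(sc))
  mapping <- if ("group" %in% names(sc)) {
    ggplot2::aes(x = .data$idx, y = .data$pc1, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$idx, y = .data$pc1)
  }
  ggplot2::ggplot(sc, mapping) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "subject", y = "PC1 score",
                  subtitle = sprintf("PC1 explains %.0f%% of variance",
                                     100 * object$variance_explained)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
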