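#' Plot state occupancy probabilities over the horizon
#'
#' Stacked-area chart of one subject's SOPs across the prediction windows,
#' one band per ordinal state.
#'
#' @param sops a [compute_sops()] matrix.
#' @return A ggplot object.
#' @export
plot_sops <- function(sops) {
  df <- as.data.frame(as.table(unclass(sops)))
  names(df) <- c("window", "state", "probability")
  df$window <- as.integer(as.character(df$window))
  df$state <- factor(df$state, levels = rev(colnames(sops)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$probability,
                                   fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::scale_fill_viridis_d(direction = -1) +
    ggplot2::labs(x = "90-day window", y = "state occupancy probability",
                  fill = "PDC state") +
    ggplot2::theme_minimal()
}

#' Plot a calibration table
#'
#' Decile points of mean observed versus mean predicted state with the
#' perfect-calibration diagonal; facets per stratum when present.
#'
#' @param calib a [subject_calibration()] table.
#' @return A ggplot object.
#' @export
plot_calibration <- function(calib) {
  p <- ggplot2::ggplot(calib, ggplot2::aes(x = .data$mean_predicted,
                                           y = .data$mean_observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "red") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean predicted state", y = "mean observed state") +
    ggplot2::theme_minimal()
  if ("stratum" %in% names(calib) && length(unique(calib$stratum)) > 1L)
    p <- p + ggplot2::facet_wrap(~stratum)
  p
}

#' Plot bootstrapped SOP distribution width over time
#'
#' One line per state: bootstrap median IQR length of the SOP distribution
#' across subjects at each window, with the 2.5-97.5 percentile envelope.
#'
#' @param boot a [bootstrap_widths()] result.
#' @return A ggplot object.
#' @export
plot_sop_width <- function(boot) {
  df <- boot$by_window
  df$state <- factor(df$state)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$median,
                                   colour = .data$state,
                                   fill = .data$state)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "90-day window", y = "SOP IQR length",
                  colour = "PDC state", fill = "PDC state") +
    ggplot2::theme_minimal()
}

#' Plot a partial-effect curve
#'
#' @param curve a [partial_effect_curve()] table.
#' @param variable label for the x axis.
#' @return A ggplot object.
#' @export
plot_partial_effect <- function(curve, variable = "predictor") {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$grid, y = .data$effect)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = variable, y = "log odds of higher PDC state") +
    ggplot2::theme_minimal()
}
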