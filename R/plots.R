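# ggplot2 graphics for rasters, training histories and avalanche scaling.

#' Raster plot of a spike train matrix
#'
#' @param S A `T x N` binary raster.
#' @param ... Unused.
#' @return A ggplot object (timestep on x, neuron on y, one point per
#'   spike).
#' @examples
#' plot_raster(diag(5L))
#' @export
plot_raster <- function(S, ...) {
  S <- assert_raster(S)
  ev <- which(S == 1L, arr.ind = TRUE)
  df <- tibble::tibble(timestep = ev[, 1], neuron = ev[, 2])
  ggplot2::ggplot(df, ggplot2::aes(.data$timestep, .data$neuron)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "timestep", y = "neuron") +
    ggplot2::theme_minimal()
}

#' Training-history plot for a PSPM fit
#'
#' Pairwise and aggregate distances from the reference, per epoch.
#'
#' @param object A `pspm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pspm_fit
#' @export
autoplot.pspm_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("d_pairwise", "d_aggregate"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "distance from reference") +
    ggplot2::theme_minimal()
}

#' Avalanche scaling plot for a criticality report
#'
#' Mean avalanche size versus duration on log-log axes, with the fitted
#' `beta_o` regression line and the `beta_p` prediction in the subtitle.
#'
#' @param object A `criticality_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot criticality_report
#' @export
autoplot.criticality_report <- function(object, ...) {
  av <- object$avalanches
  agg <- dplyr::summarise(dplyr::group_by(av, .data$duration),
                          mean_size = mean(.data$size), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(.data$duration, .data$mean_size)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "avalanche duration (steps)", y = "mean avalanche size (spikes)",
      subtitle = sprintf(
        "tau = %.3f, alpha = %.3f, beta_p = %.3f, beta_o = %.3f",
        object$tau, object$alpha, object$beta_predicted,
        object$beta_observed)) +
    ggplot2::theme_minimal()
}
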