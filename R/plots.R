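#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a bias curve
#'
#' Bias of each estimator variant against subsample size N, with point
#' ranges at plus/minus one SD of the block means and the analytic
#' predicted bias for the uncorrected complementarity statistic as a
#' dashed line. Heterogeneous replicate counts are mapped to colour.
#'
#' @param object a `bef_bias_curve` from [subsampling_experiment()].
#' @param ... unused.
#' @returns a ggplot.
#' @method autoplot bef_bias_curve
#' @export
autoplot.bef_bias_curve <- function(object, ...) {
  df <- dplyr::mutate(object, n_het = factor(.data$n_het))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$N, y = .data$mean_bias,
                                   colour = .data$n_het)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$predicted_bias),
      data = dplyr::filter(df, .data$variant == "ce_uncorrected",
                           .data$n_het == levels(df$n_het)[1]),
      linetype = 2, colour = "black") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_bias - .data$sd,
                   ymax = .data$mean_bias + .data$sd),
      position = ggplot2::position_dodge(width = 1), size = 0.25) +
    ggplot2::facet_wrap(~variant, scales = "free_y") +
    ggplot2::labs(x = "species sampled (N)", y = "bias (g/m² scale)",
                  colour = "heterogeneous\nreplicates (n)") +
    ggplot2::theme_minimal()
}

#' Quick-look plot of a community
#'
#' Scatter of the deviation in relative yield against monoculture biomass
#' with the fitted regression line — the geometry behind the partition:
#' the line's height at the mean monoculture biomass carries the
#' complementarity effect, its slope (times N Var(M)) the selection
#' effect.
#'
#' @inheritParams partition
#' @returns a ggplot.
#' @export
plot_community <- function(data, pool_size = NULL) {
  if (inherits(data, "bef_community")) data <- data$data
  dry <- compute_delta_ry(data, pool_size)
  ggplot2::ggplot(dry, ggplot2::aes(x = .data$monoculture,
                                    y = .data$delta_ry)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "monoculture biomass M (g/m²)",
                  y = "deviation in relative yield ΔRY") +
    ggplot2::theme_minimal()
}
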