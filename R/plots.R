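#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of concentration-index estimates
#'
#' One point-range per (stratum, dimension) estimate, faceted by outcome;
#' intervals are estimate +/- 1.96 SE. The dashed zero line separates
#' pro-deprived (negative) from pro-affluent (positive) concentration.
#'
#' @param object An `ineq_report` from [run_analysis()].
#' @param variant Which index variant to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ineq_report <- function(object, variant = "erreygers", ...) {
  d <- dplyr::filter(object$indices, .data$variant == !!variant)
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$estimate, y = .data$stratum, colour = .data$dimension)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      position = ggplot2::position_dodge(width = 0.6)
    ) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(
      x = sprintf("%s concentration index", tools::toTitleCase(variant)),
      y = NULL, colour = "Deprivation scale",
      title = "Socio-economic concentration of excess weight",
      subtitle = "Negative values: concentrated among the most deprived"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of Shapley contributions
#'
#' Percentage contribution of each factor to the dissimilarity index of the
#' full model.
#'
#' @param object A `shapley_decomp` from [shapley_decompose()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shapley_decomp <- function(object, ...) {
  d <- dplyr::arrange(object$factors, .data$contrib_percent)
  d$factor <- factor(d$factor, levels = d$factor)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$contrib_percent, y = .data$factor)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Contribution to explained inequality (%)", y = NULL,
      title = sprintf("Shapley decomposition of the dissimilarity index (%s)",
                      object$outcome),
      subtitle = sprintf("DI = %.3f, n = %d", object$DI, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Contribution profile across the specification ladder
#'
#' @param object A `spec_ladder` from [specification_ladder()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spec_ladder <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$specification, y = .data$contrib_percent,
                 group = .data$factor, colour = .data$factor)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = NULL, y = "Contribution (%)", colour = "Factor",
      title = sprintf("Shapley contributions across specifications (%s)",
                      object$outcome)
    ) +
    ggplot2::theme_minimal()
}
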