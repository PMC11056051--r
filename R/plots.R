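#' Plot category density trends
#'
#' Line chart of a per-1000 density (or staffing ratio) by category over the
#' panel years, with the province average dashed.
#'
#' @param series An indicator series tibble from [indicator_series()] or
#'   [category_density()].
#' @param indicator Indicator to plot (default first present).
#' @return A ggplot object.
#' @export
plot_density_trends <- function(series, indicator = NULL) {
  indicator <- indicator %||% series$indicator[1]
  df <- series[series$indicator == indicator, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$year, y = .data$value,
    colour = .data$category, linetype = .data$category == "Province"
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "dashed", `FALSE` = "solid"), guide = "none") +
    ggplot2::labs(
      x = "year", y = indicator, colour = "category",
      title = paste0(indicator, " by county category")
    ) +
    ggplot2::theme_minimal()
}

#' Plot Theil index trends with component contributions
#'
#' @param series An overall Theil series tibble from [theil_series()].
#' @return A ggplot object: one panel per resource, total index with the
#'   intra/inter components stacked beneath.
#' @export
plot_theil_trends <- function(series) {
  long <- tidyr::pivot_longer(
    series[, c("year", "resource", "ti", "ti_intra", "ti_inter")],
    cols = c("ti", "ti_intra", "ti_inter"),
    names_to = "component", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$year, y = .data$value, colour = .data$component
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$resource)) +
    ggplot2::labs(
      x = "year", y = "Theil index",
      title = "Population-weighted Theil index and its decomposition"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn ols_fit Scatter plot with the fitted line.
#' @param object An `equipanel_fit`.
#' @exportS3Method ggplot2::autoplot
autoplot.equipanel_fit <- function(object, ...) {
  df <- object$model$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope, colour = "red"
    ) +
    ggplot2::labs(
      x = object$predictor, y = object$response,
      title = sprintf(
        "%s ~ %s (%s): R² = %.2f, p = %.3g",
        object$response, object$predictor, object$scope,
        object$r_squared, object$p_value
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
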