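#' Plot a percent-change series
#'
#' Line plot of `100 * (x_t - x_base) / x_base` against year, one line per
#' variable — the standard way of showing long-run global trends in area,
#' dependence and diversity on a common scale.
#'
#' @param object A `percent_change_series` tibble (also works on the
#'   stacked output of [global_trends()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot percent_change_series
#' @export
autoplot.percent_change_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$pct_change,
                                       colour = .data$variable)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Change since base year (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot growth rates by region
#'
#' Jittered country-level growth rates per region for one of the five
#' rate variables.
#'
#' @param object A `growth_rate_table`.
#' @param variable Which rate to plot (default `"d_area"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot growth_rate_table
#' @export
autoplot.growth_rate_table <- function(object, variable = "d_area", ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df[[variable]]) & !is.na(df$region), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data[[variable]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 4,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = paste(variable, "(%/yr)")) +
    ggplot2::theme_minimal()
}

#' Plot least-squares means with letter display
#'
#' Point-and-error-bar plot of adjusted regional means (+/- 1 SE); when a
#' letters column is present (joined from [tukey_contrasts()]), levels
#' sharing a letter do not differ at the chosen alpha.
#'
#' @param object An `ls_means` tibble, optionally carrying a `letters`
#'   column.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ls_means
#' @export
autoplot.ls_means <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$level, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$estimate - .data$se,
                                          ymax = .data$estimate + .data$se)) +
    ggplot2::labs(x = NULL, y = "Least-squares mean (%/yr)") +
    ggplot2::theme_minimal()
  if ("letters" %in% names(object)) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = .data$letters, y = .data$estimate + 1.5 * .data$se),
      vjust = -0.5
    )
  }
  p
}
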