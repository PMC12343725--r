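#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cumulative onset curve
#'
#' Step plot of the Kaplan-Meier cumulative incidence from [km_curve()].
#'
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble(time = c(0, object$time), cuminc = c(0, object$cuminc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$cuminc)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time to onset (days)", y = "Cumulative incidence") +
    ggplot2::theme_minimal()
}

#' Plot a fitted Weibull onset model
#'
#' Histogram of onset intervals (density scale) with the fitted Weibull
#' density and the failure-type classification in the subtitle.
#'
#' @param object A `weibull_tto` fit.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot weibull_tto
#' @export
autoplot.weibull_tto <- function(object, bins = 40, ...) {
  df <- tibble(onset = object$data)
  grid <- tibble(x = seq(min(df$onset), max(df$onset), length.out = 400))
  grid$d <- dweibull(grid$x - object$location, object$shape, object$scale)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$onset)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$x, y = .data$d),
                       colour = "#b2182b", linewidth = 0.8) +
    ggplot2::labs(
      x = "Time to onset (days)", y = "Density",
      subtitle = sprintf("Weibull shape %.2f (95%% CI %.2f-%.2f): %s",
                         object$shape, object$shape_ci[1],
                         object$shape_ci[2], object$classification)) +
    ggplot2::theme_minimal()
}

#' Forest plot of a disproportionality screen
#'
#' ROR point estimates with 95% CIs for the terms of a screen, positives
#' highlighted. Terms with undefined ROR (zero cells) are omitted.
#'
#' @param object A `signal_screen` from [screen_signals()].
#' @param max_terms Show at most this many terms (by descending ROR).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot signal_screen
#' @export
autoplot.signal_screen <- function(object, max_terms = 30, ...) {
  df <- as_tibble(object) |>
    filter(!is.na(.data$ror)) |>
    arrange(desc(.data$ror)) |>
    head(max_terms) |>
    mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$term,
                                   colour = .data$positive)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ror_low,
                                         xmax = .data$ror_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey55"),
                                 name = "signal") +
    ggplot2::labs(x = "ROR (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot yearly report counts
#'
#' @param yearly Tibble `(year, n)` as produced by [summarize_cohort()]
#'   (the `yearly` element).
#' @return A ggplot.
#' @export
plot_report_trend <- function(yearly) {
  ggplot2::ggplot(yearly, ggplot2::aes(x = .data$year, y = .data$n)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "Receipt year", y = "Reports") +
    ggplot2::theme_minimal()
}
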