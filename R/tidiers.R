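# broom-style accessors and plots for scenario runs.

#' Tidy the per-year trajectories of a scenario run
#'
#' @param x a `scenario_run`.
#' @param ... unused.
#' @return a long tibble `(seed, year, metric, value)`.
#' @exportS3Method generics::tidy
tidy.scenario_run <- function(x, ...) {
  tidyr::pivot_longer(x$trajectories, cols = -c("seed", "year"),
                      names_to = "metric", values_to = "value")
}

#' Across-seed summary of the final simulated year
#'
#' One row per metric with the across-seed median, minimum and maximum in
#' the final year -- the summary used to report scenario outcomes.
#'
#' @param x a `scenario_run`.
#' @param ... unused.
#' @return a tibble `(metric, median, min, max, range)`.
#' @exportS3Method generics::glance
glance.scenario_run <- function(x, ...) {
  tr <- tidy(x)
  last <- max(tr$year)
  tr %>%
    filter(.data$year == last) %>%
    group_by(.data$metric) %>%
    summarise(median = stats::median(.data$value),
              min = min(.data$value), max = max(.data$value),
              range = max(.data$value) - min(.data$value),
              .groups = "drop")
}

#' Plot scenario trajectories
#'
#' Median line with the across-seed min-max ribbon, one facet per metric.
#'
#' @param object a `scenario_run`.
#' @param metrics character vector of trajectory columns to plot.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scenario_run <- function(object,
                                  metrics = c("share_young", "share_old80",
                                              "share_old100"),
                                  ...) {
  tr <- tidy(object) %>%
    filter(.data$metric %in% metrics) %>%
    group_by(.data$year, .data$metric) %>%
    summarise(med = stats::median(.data$value),
              lo = min(.data$value), hi = max(.data$value),
              .groups = "drop")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$med)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "year", y = "value") +
    ggplot2::theme_minimal()
}
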