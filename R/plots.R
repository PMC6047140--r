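#' Plot annual composite incidence rates
#'
#' Point rates with 95% CI error bars for complete-coverage years and shaded
#' ranges for adjusted incomplete-coverage years, per 1000 live births.
#'
#' @param estimates `incidence_estimate` tibble with a `year` column.
#' @param adjustments Optional `coverage_adjustment` tibble.
#' @param stratum Stratum to plot.
#' @return A ggplot object.
#' @export
plot_annual_rates <- function(estimates, adjustments = NULL,
                              stratum = "all") {
  est <- as_tibble(estimates)
  if ("stratum" %in% names(est)) {
    est <- filter(est, .data$stratum == !!stratum)
  }
  p <- ggplot2::ggplot(est, ggplot2::aes(x = .data$year, y = .data$rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(
      x = "calendar year",
      y = sprintf("brain injuries per %s live births",
                  format(est$scale[1] %||% 1000, big.mark = " ")),
      title = sprintf("Composite brain-injury incidence (%s infants)", stratum)
    )
  if (!is.null(adjustments) && nrow(adjustments)) {
    adj <- as_tibble(adjustments)
    p <- p + ggplot2::geom_errorbar(
      data = adj,
      ggplot2::aes(x = .data$year, ymin = .data$rate_low,
                   ymax = .data$rate_high),
      inherit.aes = FALSE, width = 0.3, linetype = "dashed"
    )
  }
  p
}

#' Plot per-condition annual case counts
#'
#' @param report A `surveillance_report`.
#' @return A ggplot object faceted by condition.
#' @export
plot_condition_counts <- function(report) {
  ggplot2::ggplot(report$conditions,
                  ggplot2::aes(x = .data$year, y = .data$n_all)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~condition, scales = "free_y") +
    ggplot2::labs(x = "calendar year", y = "cases",
                  title = "Conditions leading to brain injury at or soon after birth")
}

#' @exportS3Method ggplot2::autoplot
autoplot.incidence_estimate <- function(object, ...) {
  if ("year" %in% names(object)) {
    plot_annual_rates(object, ...)
  } else {
    object <- mutate(as_tibble(object), index = dplyr::row_number())
    ggplot2::ggplot(object, ggplot2::aes(x = .data$index, y = .data$rate)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                            ymax = .data$ci_high)) +
      ggplot2::labs(x = "estimate", y = "rate")
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.surveillance_report <- function(object, ...) {
  yr <- object$years
  denom <- yr$live_births
  est <- tibble(
    year = yr$year,
    rate = yr$composite_after / denom * 1000,
    ci_low = ifelse(yr$adjusted, yr$adjusted_cases_low / denom * 1000,
                    yr$composite_after / denom * 1000),
    ci_high = ifelse(yr$adjusted, yr$adjusted_cases_high / denom * 1000,
                     yr$composite_after / denom * 1000),
    scale = 1000
  )
  ggplot2::ggplot(est, ggplot2::aes(x = .data$year, y = .data$rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = "calendar year", y = "brain injuries per 1000 live births",
                  title = "Composite brain-injury incidence")
}
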