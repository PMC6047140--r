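#' Incidence rate with a log-transformed Poisson 95% confidence interval
#'
#' Computes the point rate `numerator / denominator * scale` and a 95% CI by
#' the log-transformed Poisson method: the count is treated as Poisson, the
#' interval is symmetric on the log scale,
#' `n * exp(+/- 1.96 / sqrt(n)) / d * scale`. For a zero count the lower
#' bound is 0 and the upper bound uses the exact Poisson limit
#' `3.6889 / d * scale` (the 97.5% point of a unit-mean Poisson count of
#' zero). This is the interval that reproduces the published national
#' surveillance tables.
#'
#' @param numerator Case count (vectorised).
#' @param denominator Live births in the population-year stratum; must be
#'   positive and at least the numerator.
#' @param scale Rate scale: typically 1e3 (per 1000 live births), 1e4 or 1e5.
#' @return A tibble of class `incidence_estimate` with columns `numerator`,
#'   `denominator`, `scale`, `rate`, `ci_low`, `ci_high`, `method`.
#' @export
#' @examples
#' # 2015 composite after exclusions: 5.14 (4.97 to 5.32) per 1000
#' rate_estimate(3418, 664399, scale = 1000)
rate_estimate <- function(numerator, denominator, scale = 1000) {
  if (any(is.na(numerator)) || any(numerator < 0) ||
      any(numerator != trunc(numerator))) {
    abort("`numerator` must be a non-negative count",
          class = "neosurv_rate_error")
  }
  if (any(is.na(denominator)) || any(denominator <= 0)) {
    abort("`denominator` must be positive", class = "neosurv_rate_error")
  }
  if (any(numerator > denominator)) {
    abort("`numerator` exceeds `denominator`", class = "neosurv_rate_error")
  }
  k <- pmax(length(numerator), length(denominator), length(scale))
  n <- rep_len(numerator, k)
  d <- rep_len(denominator, k)
  s <- rep_len(scale, k)

  rate <- n / d * s
  half <- exp(1.96 / sqrt(pmax(n, 1)))
  ci_low <- ifelse(n == 0, 0, n / half / d * s)
  ci_high <- ifelse(n == 0, 3.6889 / d * s, n * half / d * s)

  out <- tibble(
    numerator = n, denominator = d, scale = s,
    rate = rate, ci_low = ci_low, ci_high = ci_high,
    method = "poisson_log"
  )
  class(out) <- c("incidence_estimate", class(out))
  out
}

#' Format an incidence estimate the way the published tables print it
#'
#' @param estimate An `incidence_estimate` tibble (or any tibble with `rate`,
#'   `ci_low`, `ci_high`).
#' @param digits Decimal places; rounding is half-up, matching the published
#'   tables.
#' @return Character vector like `"5.14 (4.97 to 5.32)"`.
#' @export
format_rate <- function(estimate, digits = 2) {
  sprintf("%s (%s to %s)",
          fmt_num(estimate$rate, digits),
          fmt_num(estimate$ci_low, digits),
          fmt_num(estimate$ci_high, digits))
}

#' Format an adjusted rate range
#'
#' @param low,high Rate bounds.
#' @param digits Decimal places (half-up).
#' @return Character vector like `"4.53 to 5.19"`.
#' @export
format_range <- function(low, high, digits = 2) {
  sprintf("%s to %s", fmt_num(low, digits), fmt_num(high, digits))
}

#' Stratified incidence rates for a cohort's counts
#'
#' Joins stratified case counts with the live-birth denominator table and
#' computes one incidence estimate per requested row. Composite rates use
#' after-exclusion counts unless `phase = "before"`.
#'
#' @param counts Count tibble from [count_cases()] (columns `year`,
#'   `stratum`, `measure`, `count`).
#' @param denominators Denominator tibble with columns `year`, `stratum`,
#'   `live_births` (see [england_live_births()]); denominators are inputs,
#'   never derived from the admitted cohort, because live births are a
#'   superset of admissions.
#' @param rate_spec Tibble with columns `measure`, `stratum`, `scale` saying
#'   which rates to compute at which scale. Defaults to the composite rate
#'   per 1000 live births for all/term/preterm.
#' @param phase `"after"` (default) or `"before"`: which composite counts the
#'   `composite` measure refers to.
#' @return An `incidence_estimate` tibble with `year`, `measure`, `stratum`
#'   columns prepended.
#' @export
rates_for_cohort <- function(counts, denominators,
                             rate_spec = NULL, phase = c("after", "before")) {
  phase <- match.arg(phase)
  if (is.null(rate_spec)) {
    rate_spec <- tibble(
      measure = "composite",
      stratum = c("all", "term", "preterm"),
      scale = 1000
    )
  }
  counts <- as_tibble(counts)
  if (!"year" %in% names(counts)) counts$year <- NA_integer_
  wanted <- counts |>
    mutate(measure = case_when(
      .data$measure == paste0("composite_", phase) ~ "composite",
      TRUE ~ .data$measure
    )) |>
    inner_join(rate_spec, by = c("measure", "stratum"))

  missing_spec <- anti_join(rate_spec, wanted, by = c("measure", "stratum"))
  if (nrow(missing_spec)) {
    abort(sprintf("no counts for requested rate(s): %s",
                  paste(sprintf("%s/%s", missing_spec$measure,
                                missing_spec$stratum), collapse = ", ")),
          class = "neosurv_rate_error")
  }

  denominators <- as_tibble(denominators)
  by <- if ("year" %in% names(denominators)) c("year", "stratum") else "stratum"
  joined <- left_join(wanted, denominators, by = by)
  if (any(is.na(joined$live_births))) {
    bad <- joined[is.na(joined$live_births), c("year", "stratum")]
    abort(sprintf("missing denominator for: %s",
                  paste(sprintf("(%s, %s)", bad$year, bad$stratum),
                        collapse = ", ")),
          class = "neosurv_rate_error")
  }

  est <- rate_estimate(joined$count, joined$live_births, joined$scale)
  out <- bind_cols(joined[c("year", "measure", "stratum")], est)
  class(out) <- c("incidence_estimate", class(tibble()))
  out
}

#' Write incidence estimates as CSV
#'
#' @param estimates An `incidence_estimate` tibble.
#' @param path File path.
#' @export
write_estimates <- function(estimates, path) {
  readr::write_csv(as_tibble(estimates), path, progress = FALSE)
  invisible(path)
}
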