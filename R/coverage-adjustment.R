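#' Extreme year-over-year admission growth ratios
#'
#' From the complete-coverage years, returns the smallest and largest
#' year-over-year ratio of neonatal-unit admissions. These bound the
#' plausible inflation of an incomplete year's observed admissions, assuming
#' growth in the unobserved years was no more extreme than in the observed
#' ones.
#'
#' @param admissions Tibble with columns `year` and `admissions` for at least
#'   two consecutive complete-coverage years.
#' @return A list with `min_increase` and `max_increase` (ratios > 0).
#' @export
#' @examples
#' yearly_increase_bounds(tibble::tibble(
#'   year = 2012:2015, admissions = c(78952, 80199, 84981, 88785)
#' ))
yearly_increase_bounds <- function(admissions) {
  admissions <- arrange(as_tibble(admissions), .data$year)
  if (nrow(admissions) < 2) {
    abort("need at least two complete years", class = "neosurv_coverage_error")
  }
  if (any(diff(admissions$year) != 1)) {
    abort("complete years must be consecutive", class = "neosurv_coverage_error")
  }
  ratios <- admissions$admissions[-1] / head(admissions$admissions, -1)
  list(min_increase = min(ratios), max_increase = max(ratios))
}

#' Year-to-year variability of the case/admission proportion
#'
#' Sample standard deviation of the per-year proportion of composite
#' brain-injury cases to neonatal-unit admissions over the complete-coverage
#' years. The adjustment widens the incomplete-year proportion by two of
#' these SDs in each direction.
#'
#' @param series Tibble with columns `year`, `admissions`, `cases`.
#' @return The sample SD of `cases / admissions`.
#' @export
proportion_sd <- function(series) {
  series <- as_tibble(series)
  if (nrow(series) < 2) {
    abort("need at least two complete years", class = "neosurv_coverage_error")
  }
  if (any(series$cases > series$admissions)) {
    abort("cases exceed admissions", class = "neosurv_coverage_error")
  }
  sd(series$cases / series$admissions)
}

#' Coverage series for an incomplete-coverage year
#'
#' Bundles the observations the range adjustment needs: the target year's
#' observed admissions and cases (from participating units only), the
#' complete-coverage years' admissions and cases, and the target year's total
#' live births.
#'
#' @param complete Tibble with columns `year`, `admissions`, `cases` for the
#'   consecutive complete-coverage years.
#' @param target_year The incomplete-coverage year being adjusted.
#' @param observed_admissions,observed_cases Counts observed in the target
#'   year from the participating units.
#' @param live_births Total live births in the target year.
#' @return An object of class `coverage_series`.
#' @export
coverage_series <- function(complete, target_year, observed_admissions,
                            observed_cases, live_births) {
  complete <- arrange(as_tibble(complete), .data$year)
  if (!all(c("year", "admissions", "cases") %in% names(complete))) {
    abort("`complete` needs columns year, admissions, cases",
          class = "neosurv_coverage_error")
  }
  check_count(target_year, "target_year")
  check_count(observed_admissions, "observed_admissions")
  check_count(observed_cases, "observed_cases", positive = FALSE)
  check_count(live_births, "live_births")
  if (observed_cases > observed_admissions) {
    abort("`observed_cases` exceeds `observed_admissions`",
          class = "neosurv_coverage_error")
  }
  structure(
    list(complete = complete, target_year = as.integer(target_year),
         observed_admissions = observed_admissions,
         observed_cases = observed_cases, live_births = live_births),
    class = "coverage_series"
  )
}

#' Range adjustment for a year with incomplete registry coverage
#'
#' Implements the surveillance range estimator for years when a fraction of
#' neonatal units did not contribute data, so the observed admissions
#' undercount the true national admissions. The observed admissions are
#' inflated by the least and most extreme year-over-year growth ratios seen
#' in the complete-coverage years; the case/admission proportion is widened
#' by two sample SDs of the complete-year proportions (down for the lower
#' branch, up for the upper); adjusted case counts are the products, rounded
#' to integers, and rates divide by total live births (per 1000), under the
#' assumption that the brain-injury rate among infants in non-participating
#' units does not differ from the observed rate.
#'
#' Two guards keep the estimate coherent: inflation factors are floored at 1
#' (an "increase" cannot shrink the cohort), and the lower adjusted count is
#' floored at the observed count, since units outside the registry can only
#' add cases. A proportion driven below zero by the 2-SD shift is floored at
#' zero with a warning.
#'
#' @param series A [coverage_series()].
#' @return A one-row tibble of class `coverage_adjustment`: `year`,
#'   `observed_admissions`, `observed_cases`, `inflation_low`,
#'   `inflation_high`, `proportion`, `proportion_sd`, `adjusted_cases_low`,
#'   `adjusted_cases_high`, `rate_low`, `rate_high` (per 1000 live births).
#' @export
adjust_incomplete_year <- function(series) {
  if (!inherits(series, "coverage_series")) {
    abort("`series` must be a coverage_series", class = "neosurv_coverage_error")
  }
  bounds <- yearly_increase_bounds(series$complete[c("year", "admissions")])
  psd <- proportion_sd(series$complete)

  inflation_low <- max(1, bounds$min_increase)
  inflation_high <- max(1, bounds$max_increase)
  p_obs <- series$observed_cases / series$observed_admissions
  p_low <- p_obs - 2 * psd
  if (p_low < 0) {
    warn("lower proportion bound below zero; floored at 0")
    p_low <- 0
  }
  p_high <- p_obs + 2 * psd

  adm_low <- series$observed_admissions * inflation_low
  adm_high <- series$observed_admissions * inflation_high
  cases_low <- max(series$observed_cases, round_half_up(adm_low * p_low))
  cases_high <- max(cases_low, round_half_up(adm_high * p_high))

  out <- tibble(
    year = series$target_year,
    observed_admissions = series$observed_admissions,
    observed_cases = series$observed_cases,
    inflation_low = inflation_low, inflation_high = inflation_high,
    proportion = p_obs, proportion_sd = psd,
    adjusted_cases_low = cases_low, adjusted_cases_high = cases_high,
    rate_low = cases_low / series$live_births * 1000,
    rate_high = cases_high / series$live_births * 1000
  )
  class(out) <- c("coverage_adjustment", class(out))
  out
}
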