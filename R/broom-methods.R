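#' Tidy an incidence estimate
#'
#' @param x An `incidence_estimate`.
#' @param ... Unused.
#' @return A plain tibble, one row per estimate.
#' @exportS3Method generics::tidy
tidy.incidence_estimate <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Tidy a coverage adjustment
#'
#' @param x A `coverage_adjustment`.
#' @param ... Unused.
#' @return A plain tibble, one row per adjusted year.
#' @exportS3Method generics::tidy
tidy.coverage_adjustment <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Tidy a surveillance report
#'
#' @param x A `surveillance_report`.
#' @param ... Unused.
#' @return The long count table (`year`, `stratum`, `measure`, `count`).
#' @exportS3Method generics::tidy
tidy.surveillance_report <- function(x, ...) as_tibble(x$counts)

#' One-row summary of a pipeline run
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return A one-row tibble: years run, total admitted infants, composite
#'   cases before/after exclusions, rejected episode count.
#' @exportS3Method generics::glance
glance.pipeline_result <- function(x, ...) {
  all_counts <- filter(x$counts, .data$stratum == "all")
  tibble(
    n_years = length(unique(x$counts$year)),
    admitted_infants = sum(all_counts$count[all_counts$measure == "admitted_infants"]),
    composite_before = sum(all_counts$count[all_counts$measure == "composite_before"]),
    composite_after = sum(all_counts$count[all_counts$measure == "composite_after"]),
    episodes_rejected = sum(x$log$episodes_rejected),
    seed = x$seed
  )
}

#' One-row summary of a surveillance report
#'
#' @param x A `surveillance_report`.
#' @param ... Unused.
#' @return A one-row tibble with year span and total composite counts.
#' @exportS3Method generics::glance
glance.surveillance_report <- function(x, ...) {
  tibble(
    first_year = min(x$years$year),
    last_year = max(x$years$year),
    composite_before = sum(x$years$composite_before),
    composite_after = sum(x$years$composite_after),
    adjusted_years = sum(x$years$adjusted)
  )
}
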