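#' Assemble a publication-style surveillance report
#'
#' Combines stratified counts, complete-year incidence estimates,
#' incomplete-year range adjustments and the denominator table into the
#' layout of the national surveillance tables: one annual row per
#' gestational-age stratum carrying either a rate with 95% CI (complete
#' coverage) or an adjusted rate range (incomplete coverage), never both, and
#' a per-condition table of counts with scaled rates.
#'
#' @param counts Count tibble from [count_cases()] with a `year` column.
#' @param estimates `incidence_estimate` tibble for the complete-coverage
#'   years (composite measure).
#' @param adjustments `coverage_adjustment` rows for incomplete years, or
#'   `NULL` when every year has complete coverage.
#' @param denominators Tibble `year`, `stratum`, `live_births`.
#' @param digits Decimal places for printed rates (half-up rounding).
#' @return An object of class `surveillance_report`: list with tibbles
#'   `years` (annual composite rows) and `conditions` (per-condition counts),
#'   plus the raw `counts`.
#' @export
build_report <- function(counts, estimates, adjustments = NULL,
                         denominators = england_live_births(), digits = 2) {
  counts <- as_tibble(counts)
  if (!"year" %in% names(counts)) {
    abort("`counts` must carry a year column", class = "neosurv_report_error")
  }
  years <- sort(unique(counts$year))
  est_years <- unique(estimates$year)
  adj_years <- if (is.null(adjustments)) integer(0) else unique(adjustments$year)

  if (length(intersect(est_years, adj_years))) {
    abort(sprintf("year(s) with both a CI estimate and a coverage adjustment: %s",
                  paste(intersect(est_years, adj_years), collapse = ", ")),
          class = "neosurv_report_error")
  }
  uncovered <- setdiff(years, union(est_years, adj_years))
  extra <- setdiff(union(est_years, adj_years), years)
  if (length(extra)) {
    abort(sprintf("estimates/adjustments for year(s) absent from counts: %s",
                  paste(extra, collapse = ", ")),
          class = "neosurv_report_error")
  }

  wide <- counts |>
    filter(.data$stratum == "all",
           .data$measure %in% c("admitted_infants", "composite_before",
                                "composite_after", "n_excluded")) |>
    tidyr::pivot_wider(names_from = "measure", values_from = "count")

  denom_all <- denominators |> filter(.data$stratum == "all")
  est_all <- estimates |>
    filter(.data$stratum == "all") |>
    mutate(rate_text = format_rate(pick(everything()), digits)) |>
    select("year", "rate_text")

  year_rows <- wide |>
    left_join(denom_all[c("year", "live_births")], by = "year") |>
    left_join(est_all, by = "year")
  if (!is.null(adjustments)) {
    adj <- as_tibble(adjustments) |>
      mutate(range_text = format_range(.data$rate_low, .data$rate_high, digits)) |>
      select("year", adjusted_cases_low = "adjusted_cases_low",
             adjusted_cases_high = "adjusted_cases_high",
             range_text = "range_text")
    year_rows <- left_join(year_rows, adj, by = "year")
  } else {
    year_rows <- mutate(year_rows, adjusted_cases_low = NA_real_,
                        adjusted_cases_high = NA_real_,
                        range_text = NA_character_)
  }
  year_rows <- year_rows |>
    mutate(
      adjusted = .data$year %in% adj_years,
      rate = dplyr::coalesce(.data$rate_text, .data$range_text,
                             "not estimated")
    ) |>
    select(-"rate_text", -"range_text") |>
    arrange(.data$year)

  cond_counts <- counts |>
    filter(.data$measure %in% c(condition_names(), "severe_pivh"),
           .data$stratum %in% c("all", "term", "preterm")) |>
    tidyr::pivot_wider(names_from = "stratum", values_from = "count",
                       names_prefix = "n_") |>
    rename(condition = "measure") |>
    arrange(.data$condition, .data$year)

  structure(
    list(years = year_rows, conditions = cond_counts, counts = counts,
         uncovered_years = uncovered),
    class = "surveillance_report"
  )
}

#' @export
print.surveillance_report <- function(x, ...) {
  cat("Brain injuries occurring at or soon after birth: annual surveillance\n")
  cat(strrep("-", 68), "\n", sep = "")
  hdr <- sprintf("%5s %10s %12s %8s %9s %8s %-22s",
                 "year", "admitted", "live births", "before", "excluded",
                 "after", "rate/1000 live births")
  cat(hdr, "\n")
  for (i in seq_len(nrow(x$years))) {
    r <- x$years[i, ]
    cat(sprintf("%5d %10s %12s %8s %9s %8s %-22s",
                r$year,
                format(r$admitted_infants, big.mark = " "),
                format(r$live_births, big.mark = " "),
                format(r$composite_before, big.mark = " "),
                format(r$n_excluded, big.mark = " "),
                format(r$composite_after, big.mark = " "),
                paste0(r$rate, if (r$adjusted) " (adjusted range)" else "")),
        "\n")
  }
  if (length(x$uncovered_years)) {
    cat("years without rate estimates:",
        paste(x$uncovered_years, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write the report tables as CSV
#'
#' @param report A `surveillance_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$years, file.path(dir, "annual_summary.csv"),
                   progress = FALSE)
  readr::write_csv(report$conditions, file.path(dir, "condition_counts.csv"),
                   progress = FALSE)
  readr::write_csv(report$counts, file.path(dir, "counts.csv"),
                   progress = FALSE)
  invisible(dir)
}
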