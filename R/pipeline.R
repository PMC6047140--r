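#' Configuration for a multi-year synthetic surveillance run
#'
#' Study conditions for an end-to-end surveillance simulation over several
#' calendar years. Defaults mirror the published England series 2010-2015:
#' per-year live births from the national denominators, admission
#' probabilities scaled per year to the published admissions/births ratios
#' (back-extrapolated at the mean complete-year growth for 2010-2011), a
#' per-year prevalence drift following the published cases/admissions
#' proportions, and incomplete registry coverage (90% of units participating)
#' in 2010-2011.
#'
#' @param years Calendar years to simulate.
#' @param scale Multiplier on the per-year live births; use small values
#'   (e.g. 0.03) for fast test cohorts.
#' @param incomplete_years Years in which only `participation` of the units
#'   contribute records.
#' @param participation Fraction of units contributing in incomplete years.
#' @param n_units Number of neonatal units.
#' @param dup_rate,out_of_range_rate Data-defect rates injected before
#'   cleaning (set both to 0 for pristine records).
#' @param base Baseline [cohort_config()] arguments as a named list,
#'   overriding the 2015-calibrated defaults.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(years = 2010:2015, scale = 1,
                            incomplete_years = c(2010, 2011),
                            participation = 0.9, n_units = 160,
                            dup_rate = 0.002, out_of_range_rate = 0.001,
                            base = list()) {
  if (!all(incomplete_years %in% years)) {
    abort("`incomplete_years` must be a subset of `years`",
          class = "neosurv_config_error")
  }
  pub <- nnrd_annual_counts() |> filter(.data$stratum == "all")
  pre <- nnrd_annual_counts() |> filter(.data$stratum == "preterm")

  # published admissions/births ratios for the complete years, normalised to
  # 2015; incomplete years back-extrapolated at the mean complete-year growth
  rate_by_year <- setNames(pub$admissions / pub$live_births, pub$year)
  complete_pub <- as.character(2012:2015)
  growth <- mean(rate_by_year[complete_pub][-1] /
                   head(rate_by_year[complete_pub], -1))
  mult <- rate_by_year / rate_by_year["2015"]
  mult["2011"] <- mult["2012"] / growth
  mult["2010"] <- mult["2012"] / growth^2

  # published composite proportion per year, normalised to 2015
  prop <- setNames(pub$cases_after / pub$admissions, pub$year)
  drift <- prop / prop["2015"]

  lb <- setNames(pub$live_births, pub$year)
  pf <- setNames(pre$live_births / pub$live_births, pub$year)

  missing <- setdiff(as.character(years), names(lb))
  if (length(missing)) {
    abort(sprintf("no default calibration for year(s) %s; use years 2010-2015",
                  paste(missing, collapse = ", ")),
          class = "neosurv_config_error")
  }

  structure(
    list(
      years = as.integer(years), scale = scale,
      incomplete_years = as.integer(incomplete_years),
      participation = participation, n_units = as.integer(n_units),
      dup_rate = dup_rate, out_of_range_rate = out_of_range_rate,
      live_births = lb[as.character(years)],
      preterm_fraction = pf[as.character(years)],
      admission_multiplier = mult[as.character(years)],
      prevalence_multiplier = drift[as.character(years)],
      base = base
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may set any argument of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

year_seed <- function(seed, year, stage = 0L) {
  as.integer((abs(seed) + 7919 * (year - 2000) + 104729 * stage) %%
               (.Machine$integer.max - 1L))
}

cohort_config_for_year <- function(config, year, seed) {
  yr <- as.character(year)
  prev <- default_prevalences()
  m <- config$prevalence_multiplier[[yr]]
  prev$term <- pmin(1, prev$term * m)
  prev$preterm <- pmin(1, prev$preterm * m)
  args <- list(
    year = year,
    n_live_births = max(1, round(config$live_births[[yr]] * config$scale)),
    preterm_fraction = config$preterm_fraction[[yr]],
    admission_prob_term = min(1, (55045 / 609076) *
                                config$admission_multiplier[[yr]]),
    admission_prob_preterm = min(1, (33740 / 50308) *
                                   config$admission_multiplier[[yr]]),
    condition_prevalences = prev,
    n_units = config$n_units,
    seed = year_seed(seed, year)
  )
  do.call(cohort_config, modifyList(args, config$base))
}

#' Run the surveillance pipeline end to end on synthetic cohorts
#'
#' Simulates one cohort per configured year, injects data defects, masks
#' non-participating units in incomplete-coverage years, cleans and merges
#' the episode records, ascertains composite cases, computes incidence rates
#' with 95% CIs for complete-coverage years and range adjustments for
#' incomplete ones, and assembles the surveillance report. Fully
#' deterministic given `seed`.
#'
#' @param config A [pipeline_config()] (or path to a YAML file for
#'   [read_pipeline_config()]).
#' @param seed Integer seed driving every stage.
#' @param catalog A [condition_catalog()].
#' @param out_dir If given, report tables are written there as CSV.
#' @param quiet Suppress per-stage record-count logging?
#' @return An object of class `pipeline_result`: list with the
#'   `surveillance_report`, the stage tibbles (`counts`, `estimates`,
#'   `adjustments`, `denominators`), the per-year ground truth counts
#'   (`truth_counts`) and a per-stage `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         catalog = condition_catalog(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config", class = "neosurv_config_error")
  }
  say <- function(...) if (!quiet) inform(sprintf(...))

  counts <- list(); denoms <- list(); truths <- list(); logs <- list()
  for (year in config$years) {
    cfg <- cohort_config_for_year(config, year, seed)
    cohort <- generate_cohort(cfg, catalog)
    episodes <- cohort$episodes
    n_gen <- nrow(episodes)

    dirty <- inject_dirty_records(episodes, config$dup_rate,
                                  config$out_of_range_rate,
                                  seed = year_seed(seed, year, 1L))
    episodes <- dirty$episodes

    masked <- 0L
    if (year %in% config$incomplete_years) {
      units <- sprintf("U%03d", seq_len(config$n_units))
      participating <- withr::with_seed(
        year_seed(seed, year, 2L),
        sample(units, size = max(1, round(config$participation *
                                            config$n_units)))
      )
      before <- nrow(episodes)
      episodes <- apply_coverage_mask(episodes, participating)
      masked <- before - nrow(episodes)
    }

    cleaned <- clean_episodes(episodes)
    infants <- merge_to_infants(cleaned$retained)
    results <- classify_infants(infants, catalog, warn_unknown = FALSE)
    counts[[as.character(year)]] <- count_cases(results)
    denoms[[as.character(year)]] <- cohort$truth$live_births |>
      mutate(year = year, live_births = .data$live_births, .before = 1) |>
      select("year", "stratum", "live_births")
    truths[[as.character(year)]] <- cohort$truth$counts
    logs[[as.character(year)]] <- tibble(
      year = year, episodes_generated = n_gen,
      episodes_injected = nrow(dirty$injected), episodes_masked = masked,
      episodes_rejected = nrow(cleaned$rejects), infants = nrow(infants)
    )
    say("year %d: %d episodes generated, %d injected, %d masked, %d rejected, %d infants",
        year, n_gen, nrow(dirty$injected), masked, nrow(cleaned$rejects),
        nrow(infants))
  }

  counts <- bind_rows(counts)
  denominators <- bind_rows(denoms)
  complete_years <- setdiff(config$years, config$incomplete_years)

  estimates <- rates_for_cohort(
    filter(counts, .data$year %in% complete_years),
    denominators
  )

  adjustments <- NULL
  if (length(config$incomplete_years)) {
    all_counts <- counts |>
      filter(.data$stratum == "all") |>
      tidyr::pivot_wider(names_from = "measure", values_from = "count")
    complete_series <- all_counts |>
      filter(.data$year %in% complete_years) |>
      transmute(.data$year, admissions = .data$admitted_infants,
                cases = .data$composite_after)
    adjustments <- purrr::map(config$incomplete_years, function(y) {
      obs <- all_counts[all_counts$year == y, ]
      lb <- denominators$live_births[denominators$year == y &
                                       denominators$stratum == "all"]
      adjust_incomplete_year(coverage_series(
        complete_series, y, obs$admitted_infants, obs$composite_after, lb
      ))
    }) |> bind_rows()
  }

  report <- build_report(counts, estimates, adjustments, denominators)
  if (!is.null(out_dir)) write_report(report, out_dir)

  structure(
    list(report = report, counts = counts, estimates = estimates,
         adjustments = adjustments, denominators = denominators,
         truth_counts = bind_rows(truths), log = bind_rows(logs),
         seed = seed),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
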