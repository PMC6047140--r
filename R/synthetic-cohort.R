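#' Default per-admitted-infant condition prevalences
#'
#' Probabilities that an admitted infant carries each condition of the
#' composite definition, separately for term and preterm infants. The
#' defaults are calibrated to the published 2015 England surveillance counts
#' (per-condition cases divided by admitted infants in each stratum);
#' bilirubin encephalopathy among preterm infants uses 2012, the last year
#' with a non-zero count. cPVL is a preterm-only condition, so its term
#' prevalence is fixed at zero.
#'
#' @return A tibble with columns `condition`, `term`, `preterm`.
#' @export
default_prevalences <- function() {
  tribble(
    ~condition, ~term, ~preterm,
    "seizures", 919 / 55045, 330 / 33740,
    "intracranial_haemorrhage", 117 / 55045, 609 / 33740,
    "stroke", 76 / 55045, 14 / 33740,
    "hie", 1417 / 55045, 325 / 33740,
    "cns_infection", 277 / 55045, 188 / 33740,
    "bilirubin_encephalopathy", 4 / 55045, 2 / 32752,
    "cpvl", 0, 184 / 33740
  )
}

# Gestational-age weights for admitted preterm infants, 23..36 completed
# weeks, weighted toward 32-36 so the <32 and <34 subgroups are populated at
# plausible admitted-cohort shares (~a quarter below 32 weeks).
preterm_ga_weights <- function() {
  w <- c(1, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 10, 14, 18, 22)
  names(w) <- 23:36
  w / sum(w)
}

#' Configuration for a synthetic neonatal cohort-year
#'
#' Parameters for one calendar year of synthetic episode-level neonatal-unit
#' records emulating a national registry: live births split into term/preterm
#' strata, stratum-specific admission probabilities, per-admitted-infant
#' condition prevalences, congenital-exclusion codes among seizure cases,
#' multi-episode infants and uniform assignment of infants to neonatal units.
#' Defaults reproduce the scale of the published 2015 England cohort
#' (664 399 live births, ~89 000 admissions).
#'
#' @param year Calendar year of the cohort.
#' @param n_live_births Live births in the population-year (denominator).
#' @param preterm_fraction Proportion of live births below 37 weeks.
#' @param admission_prob_term,admission_prob_preterm Probability that a
#'   term/preterm live birth is admitted for neonatal care.
#' @param condition_prevalences Tibble as [default_prevalences()]: per
#'   admitted infant probabilities by stratum.
#' @param seizure_hie_rr Relative risk of seizures given HIE, exercising
#'   condition co-occurrence while preserving the marginal seizure
#'   prevalence. 1 means independence.
#' @param exclusion_prob_given_seizure Probability that a seizure case also
#'   carries a congenital-exclusion diagnosis.
#' @param multi_episode_prob Probability that an admitted infant has a second
#'   care episode.
#' @param n_units Number of neonatal units; infants are assigned uniformly.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A validated object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_live_births = 5000, seed = 1)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort$truth$infants)
cohort_config <- function(year = 2015,
                          n_live_births = 664399,
                          preterm_fraction = 50308 / 664399,
                          admission_prob_term = 55045 / 609076,
                          admission_prob_preterm = 33740 / 50308,
                          condition_prevalences = default_prevalences(),
                          seizure_hie_rr = 5,
                          exclusion_prob_given_seizure = 0.025,
                          multi_episode_prob = 0.3,
                          n_units = 160,
                          seed = 1L) {
  check_count(year, "year")
  check_count(n_live_births, "n_live_births")
  check_prob(preterm_fraction, "preterm_fraction")
  check_prob(admission_prob_term, "admission_prob_term")
  check_prob(admission_prob_preterm, "admission_prob_preterm")
  check_prob(exclusion_prob_given_seizure, "exclusion_prob_given_seizure")
  check_prob(multi_episode_prob, "multi_episode_prob")
  check_count(n_units, "n_units")
  check_count(seed, "seed", positive = FALSE)

  prev <- as_tibble(condition_prevalences)
  if (!all(c("condition", "term", "preterm") %in% names(prev))) {
    abort("`condition_prevalences` needs columns condition, term, preterm",
          class = "neosurv_config_error")
  }
  check_prob(prev$term, "condition_prevalences$term")
  check_prob(prev$preterm, "condition_prevalences$preterm")
  if (!"cpvl" %in% prev$condition || prev$term[prev$condition == "cpvl"] != 0) {
    abort("`condition_prevalences`: cpvl term prevalence must be 0 (preterm-only condition)",
          class = "neosurv_config_error")
  }
  if (!is.numeric(seizure_hie_rr) || seizure_hie_rr < 0) {
    abort("`seizure_hie_rr` must be a non-negative number",
          class = "neosurv_config_error")
  }
  p_s <- prev[prev$condition == "seizures", c("term", "preterm")]
  p_h <- prev[prev$condition == "hie", c("term", "preterm")]
  if (any(seizure_hie_rr * unlist(p_s) > 1) ||
      any(seizure_hie_rr * unlist(p_h) > 1)) {
    abort("`seizure_hie_rr` too large for the configured seizure/HIE prevalences",
          class = "neosurv_config_error")
  }

  structure(
    list(
      year = as.integer(year), n_live_births = as.integer(n_live_births),
      preterm_fraction = preterm_fraction,
      admission_prob_term = admission_prob_term,
      admission_prob_preterm = admission_prob_preterm,
      condition_prevalences = prev,
      seizure_hie_rr = seizure_hie_rr,
      exclusion_prob_given_seizure = exclusion_prob_given_seizure,
      multi_episode_prob = multi_episode_prob,
      n_units = as.integer(n_units), seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort-year with known ground truth
#'
#' Simulates one calendar year of episode-level neonatal-unit records and the
#' matching per-infant ground truth. Every admitted infant has at least one
#' episode; infants drawn as multi-episode have two, with consistent
#' infant-level fields and their diagnosis tokens distributed (possibly
#' redundantly) across the episodes. Conditions are sampled as Bernoulli
#' draws per admitted infant within stratum, with a configurable
#' seizure-given-HIE relative risk that preserves the marginal seizure
#' prevalence. Seizure cases additionally draw a congenital-exclusion token
#' with the configured probability. Output is deterministic given the config
#' seed.
#'
#' @param config A [cohort_config()].
#' @param catalog A [condition_catalog()] supplying the tokens written into
#'   the records.
#' @return A list of class `neonatal_cohort`:
#'   * `episodes`: tibble in the episode CSV dialect (`infant_id`, `unit_id`,
#'     `year`, `admission_date`, `discharge_date`, `gestational_weeks`,
#'     `codes` as semicolon-separated tokens);
#'   * `truth`: list with `infants` (per-infant true flags, unit, composite
#'     status before/after exclusions), `counts` (true counts by stratum) and
#'     `live_births` (realised denominator by stratum).
#' @export
generate_cohort <- function(config, catalog = condition_catalog()) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be a cohort_config", class = "neosurv_config_error")
  }
  catalog <- validate_catalog(catalog)

  withr::with_seed(config$seed, {
    n_pre_births <- rbinom(1, config$n_live_births, config$preterm_fraction)
    n_term_births <- config$n_live_births - n_pre_births
    n_term <- rbinom(1, n_term_births, config$admission_prob_term)
    n_pre <- rbinom(1, n_pre_births, config$admission_prob_preterm)
    n <- n_term + n_pre

    stratum <- rep(c("term", "preterm"), c(n_term, n_pre))
    ga <- c(
      sample(37:41, n_term, replace = TRUE),
      sample(23:36, n_pre, replace = TRUE, prob = preterm_ga_weights())
    )
    infant_id <- sprintf("%d-%06d", config$year, seq_len(max(n, 0)))
    unit_id <- sprintf("U%03d", sample.int(config$n_units, n, replace = TRUE))

    prev <- config$condition_prevalences
    p_of <- function(cond) {
      row <- prev[prev$condition == cond, ]
      ifelse(stratum == "term", row$term, row$preterm)
    }

    p_hie <- p_of("hie")
    hie <- runif(n) < p_hie
    # Seizures with elevated risk given HIE; probability off HIE is solved so
    # the marginal seizure prevalence stays at the configured value.
    p_sz <- p_of("seizures")
    rr <- config$seizure_hie_rr
    p_sz_hie <- pmin(1, rr * p_sz)
    p_sz_nohie <- pmax(0, (p_sz - p_sz_hie * p_hie) / pmax(1 - p_hie, 1e-12))
    seizures <- runif(n) < ifelse(hie, p_sz_hie, p_sz_nohie)

    flags <- tibble(
      seizures = seizures,
      intracranial_haemorrhage = runif(n) < p_of("intracranial_haemorrhage"),
      stroke = runif(n) < p_of("stroke"),
      hie = hie,
      cns_infection = runif(n) < p_of("cns_infection"),
      bilirubin_encephalopathy = runif(n) < p_of("bilirubin_encephalopathy"),
      cpvl = runif(n) < p_of("cpvl")
    )
    has_exclusion_code <- flags$seizures &
      runif(n) < config$exclusion_prob_given_seizure

    flag_mat <- as.matrix(flags)
    composite_before <- rowSums(flag_mat) > 0
    seizure_only <- flags$seizures & rowSums(flag_mat) == 1
    composite_after <- composite_before & !(seizure_only & has_exclusion_code)

    # one sampled token per condition held
    codes <- rep("", n)
    for (cond in names(catalog$conditions)) {
      idx <- which(flags[[cond]])
      if (!length(idx)) next
      toks <- catalog$conditions[[cond]]$tokens
      drawn <- toks[sample.int(length(toks), length(idx), replace = TRUE)]
      codes[idx] <- paste(codes[idx], drawn, sep = ";")
    }
    idx <- which(has_exclusion_code)
    if (length(idx)) {
      drawn <- catalog$exclusions[
        sample.int(length(catalog$exclusions), length(idx), replace = TRUE)]
      codes[idx] <- paste(codes[idx], drawn, sep = ";")
    }
    codes <- sub("^;", "", codes)

    multi <- runif(n) < config$multi_episode_prob
    episodes <- build_episodes(config, infant_id, unit_id, ga, stratum,
                               codes, multi)

    infants <- bind_cols(
      tibble(infant_id = infant_id, unit_id = unit_id, stratum = stratum,
             gestational_weeks = ga),
      flags,
      tibble(has_exclusion_code = has_exclusion_code,
             composite_before = composite_before,
             composite_after = composite_after,
             n_episodes = ifelse(multi, 2L, 1L))
    )

    truth <- list(
      infants = infants,
      counts = truth_counts(infants, config$year),
      live_births = tibble(
        stratum = c("all", "term", "preterm"),
        live_births = c(config$n_live_births, n_term_births, n_pre_births)
      )
    )
    structure(list(episodes = episodes, truth = truth),
              class = "neonatal_cohort")
  })
}

# Assemble the episode table: admission dates uniform over the year,
# stratum-dependent length of stay, a second episode for multi-episode
# infants with the infant's tokens split across episodes (each token going to
# the first, the second or both).
build_episodes <- function(config, infant_id, unit_id, ga, stratum, codes,
                           multi) {
  n <- length(infant_id)
  year_start <- as.Date(sprintf("%d-01-01", config$year))
  year_end <- as.Date(sprintf("%d-12-31", config$year))
  if (n == 0) {
    return(tibble(
      infant_id = character(), unit_id = character(), year = integer(),
      admission_date = as.Date(character()),
      discharge_date = as.Date(character()),
      gestational_weeks = integer(), codes = character()
    ))
  }

  adm1 <- year_start + sample.int(320, n, replace = TRUE) - 1
  los1 <- rpois(n, ifelse(stratum == "term", 5, 20)) + 1
  dis1 <- pmin(adm1 + los1, year_end)

  code_list <- split_codes(codes)
  ep1_codes <- codes
  ep2 <- NULL
  if (any(multi)) {
    midx <- which(multi)
    # token-level assignment: 1 = first episode, 2 = second, 3 = both
    assign_codes <- function(toks) {
      if (!length(toks)) return(list(e1 = character(), e2 = character()))
      a <- sample.int(3, length(toks), replace = TRUE)
      list(e1 = toks[a != 2], e2 = toks[a != 1])
    }
    split <- lapply(code_list[midx], assign_codes)
    ep1_codes[midx] <- join_codes(lapply(split, `[[`, "e1"))
    gap <- sample.int(5, length(midx), replace = TRUE)
    adm2 <- pmin(dis1[midx] + gap, year_end)
    los2 <- rpois(length(midx), ifelse(stratum[midx] == "term", 5, 15)) + 1
    dis2 <- pmin(adm2 + los2, year_end)
    ep2 <- tibble(
      infant_id = infant_id[midx], unit_id = unit_id[midx],
      year = config$year, admission_date = adm2, discharge_date = dis2,
      gestational_weeks = ga[midx],
      codes = join_codes(lapply(split, `[[`, "e2"))
    )
  }

  ep1 <- tibble(
    infant_id = infant_id, unit_id = unit_id, year = config$year,
    admission_date = adm1, discharge_date = dis1,
    gestational_weeks = ga, codes = ep1_codes
  )
  bind_rows(ep1, ep2) |> arrange(.data$infant_id, .data$admission_date)
}

condition_names <- function() {
  c("seizures", "intracranial_haemorrhage", "stroke", "hie", "cns_infection",
    "bilirubin_encephalopathy", "cpvl")
}

truth_counts <- function(infants, year) {
  strata <- list(
    all = rep(TRUE, nrow(infants)),
    term = infants$stratum == "term",
    preterm = infants$stratum == "preterm",
    lt32 = infants$gestational_weeks < 32,
    lt34 = infants$gestational_weeks < 34
  )
  purrr::imap(strata, function(keep, nm) {
    sub <- infants[keep, , drop = FALSE]
    tibble(
      year = year, stratum = nm,
      measure = c("admitted_infants", "composite_before", "composite_after",
                  condition_names()),
      count = c(nrow(sub), sum(sub$composite_before), sum(sub$composite_after),
                vapply(condition_names(), function(cond) sum(sub[[cond]]),
                       numeric(1)))
    )
  }) |> bind_rows()
}

#' Restrict episodes to participating neonatal units
#'
#' Emulates registry under-coverage: only episodes from participating units
#' are observed. Records are filtered, never mutated, so an infant whose unit
#' did not participate disappears from the observed cohort entirely.
#'
#' @param episodes Episode tibble.
#' @param participating_units Character vector of unit ids contributing data.
#' @return The episodes from participating units.
#' @export
apply_coverage_mask <- function(episodes, participating_units) {
  if (length(participating_units) == 0) {
    abort("`participating_units` is empty: no observable cohort",
          class = "neosurv_coverage_error")
  }
  filter(episodes, .data$unit_id %in% participating_units)
}

#' Inject duplicate and out-of-range episodes
#'
#' Adds data-quality defects of the kinds a registry's cleaning step must
#' handle: exact duplicate episodes, and corrupted copies with impossible
#' values (gestational age of 99 weeks, or discharge before admission). The
#' original rows are kept untouched; the injected rows are returned in a
#' sidecar so tests can check that cleaning rejects exactly them.
#'
#' @param episodes Episode tibble (assumed free of exact duplicates, as
#'   produced by [generate_cohort()]).
#' @param dup_rate Per-episode probability of injecting one exact duplicate.
#' @param out_of_range_rate Per-episode probability of injecting one
#'   corrupted copy.
#' @param seed Integer seed.
#' @return A list with `episodes` (original rows followed by injected rows)
#'   and `injected` (the injected rows with a `defect` column:
#'   `"duplicate"`, `"gestation_out_of_range"` or `"date_inversion"`).
#' @export
inject_dirty_records <- function(episodes, dup_rate = 0.01,
                                 out_of_range_rate = 0.005, seed = 1L) {
  check_prob(dup_rate, "dup_rate")
  check_prob(out_of_range_rate, "out_of_range_rate")
  withr::with_seed(seed, {
    n <- nrow(episodes)
    dup_idx <- which(runif(n) < dup_rate)
    dups <- episodes[dup_idx, , drop = FALSE]

    oor_idx <- which(runif(n) < out_of_range_rate)
    oor <- episodes[oor_idx, , drop = FALSE]
    defect <- character(nrow(oor))
    if (nrow(oor)) {
      kind <- sample(c("gestation_out_of_range", "date_inversion"),
                     nrow(oor), replace = TRUE)
      ga_rows <- kind == "gestation_out_of_range"
      oor$gestational_weeks[ga_rows] <- 99L
      inv <- which(!ga_rows)
      oor$discharge_date[inv] <- oor$admission_date[inv] -
        sample.int(10, length(inv), replace = TRUE)
      defect <- kind
    }

    injected <- bind_rows(
      mutate(dups, defect = if (nrow(dups)) "duplicate" else character(0)),
      mutate(oor, defect = defect)
    )
    list(
      episodes = bind_rows(episodes, select(injected, -"defect")),
      injected = injected
    )
  })
}

#' @export
print.neonatal_cohort <- function(x, ...) {
  cat(sprintf(
    "<neonatal_cohort> year %d: %d episodes, %d admitted infants (%d term, %d preterm)\n",
    x$episodes$year[1] %||% NA_integer_, nrow(x$episodes),
    nrow(x$truth$infants), sum(x$truth$infants$stratum == "term"),
    sum(x$truth$infants$stratum == "preterm")
  ))
  cat(sprintf("  true composite cases: %d before / %d after exclusions\n",
              sum(x$truth$infants$composite_before),
              sum(x$truth$infants$composite_after)))
  invisible(x)
}
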