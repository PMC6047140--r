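# Shared fixtures: a hand-rolled episode builder, a small cohort config and
# a deliberately naive classification oracle (explicit loops, re-derived
# rule logic) kept independent of the package's vectorised implementation.

episode_columns <- function() {
  c("infant_id", "unit_id", "year", "admission_date", "discharge_date",
    "gestational_weeks", "codes")
}

make_episode <- function(infant_id = "a", unit_id = "U001", year = 2015L,
                         admission = "2015-03-01", discharge = "2015-03-05",
                         ga = 40L, codes = "") {
  tibble::tibble(
    infant_id = infant_id, unit_id = unit_id, year = as.integer(year),
    admission_date = as.Date(admission), discharge_date = as.Date(discharge),
    gestational_weeks = as.integer(ga), codes = codes
  )
}

small_config <- function(seed = 1L, ...) {
  cohort_config(n_live_births = 20000, seed = seed, ...)
}

zero_prevalences <- function() {
  prev <- default_prevalences()
  prev$term <- 0
  prev$preterm <- 0
  prev
}

# Brute-force oracle: enumerate conditions and tokens with loops.
oracle_classify <- function(infants, catalog = condition_catalog()) {
  out <- list()
  for (i in seq_len(nrow(infants))) {
    codes <- strsplit(infants$codes[i], ";", fixed = TRUE)[[1]]
    codes <- codes[nzchar(codes)]
    ga <- infants$gestational_weeks[i]
    flags <- logical(0)
    for (cond in names(catalog$conditions)) {
      hit <- FALSE
      for (tok in catalog$conditions[[cond]]$tokens) {
        if (tok %in% codes) hit <- TRUE
      }
      if (identical(catalog$conditions[[cond]]$restriction, "preterm") &&
          (is.na(ga) || ga >= 37)) {
        hit <- FALSE
      }
      flags[[cond]] <- hit
    }
    has_excl <- FALSE
    for (tok in catalog$exclusions) if (tok %in% codes) has_excl <- TRUE
    before <- any(flags)
    seizure_only <- isTRUE(flags[["seizures"]]) && sum(flags) == 1
    after <- before && !(seizure_only && has_excl)
    out[[i]] <- tibble::tibble(
      infant_id = infants$infant_id[i],
      !!!as.list(flags),
      composite_before = before, composite_after = after
    )
  }
  dplyr::bind_rows(out)
}

# Random tiny infant table over catalog + unknown tokens, for oracle checks.
random_small_infants <- function(n = 12, max_codes = 3,
                                 catalog = condition_catalog()) {
  vocab <- c(
    unlist(lapply(catalog$conditions, `[[`, "tokens"), use.names = FALSE),
    catalog$exclusions, "unrelated_code_1", "unrelated_code_2"
  )
  codes <- vapply(seq_len(n), function(i) {
    k <- sample(0:max_codes, 1)
    paste(sample(vocab, k), collapse = ";")
  }, character(1))
  tibble::tibble(
    infant_id = sprintf("i%02d", seq_len(n)),
    year = 2015L,
    gestational_weeks = sample(c(24:42, NA), n, replace = TRUE),
    codes = codes
  )
}
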