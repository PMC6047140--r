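infants_from <- function(...) {
  rows <- list(...)
  tibble::tibble(
    infant_id = sprintf("i%d", seq_along(rows)),
    year = 2015L,
    gestational_weeks = vapply(rows, `[[`, integer(1), "ga"),
    codes = vapply(rows, `[[`, character(1), "codes")
  )
}

test_that("population restriction: cPVL never counts for term infants", {
  inf <- infants_from(
    list(ga = 40L, codes = "cystic_pvl"),
    list(ga = 30L, codes = "cystic_pvl"),
    list(ga = 40L, codes = "")
  )
  res <- classify_infants(inf)
  expect_false(res$cpvl[1])
  expect_false(res$composite_before[1])
  expect_true(res$cpvl[2])
  expect_true(res$composite_before[2])
  expect_false(res$composite_before[3])
})

test_that("unknown codes are ignored with a warning, never a crash", {
  inf <- infants_from(list(ga = 40L, codes = "made_up_code;seizure_clinical"))
  expect_warning(res <- classify_infants(inf), "made_up_code")
  expect_true(res$seizures[1])
  expect_silent(classify_infants(inf, warn_unknown = FALSE))
})

test_that("classifier agrees with the brute-force oracle on random cohorts", {
  catalog <- condition_catalog()
  withr::with_seed(99, {
    for (rep in 1:40) {
      inf <- random_small_infants(n = 12, max_codes = 3, catalog = catalog)
      got <- classify_infants(inf, catalog, warn_unknown = FALSE)
      want <- oracle_classify(inf, catalog)
      for (cond in condition_flags()) {
        expect_identical(got[[cond]], want[[cond]])
      }
      expect_identical(got$composite_before, want$composite_before)
      expect_identical(got$composite_after, want$composite_after)
    }
  })
})

test_that("the congenital exclusion removes seizure-only cases exactly", {
  inf <- infants_from(
    list(ga = 40L, codes = "seizure_clinical;congenital_infection"),
    list(ga = 40L, codes = "seizure_clinical;hie_moderate;congenital_infection"),
    list(ga = 40L, codes = "hie_moderate;congenital_infection"),
    list(ga = 40L, codes = "seizure_clinical")
  )
  res <- classify_infants(inf)
  # seizures only + congenital token: counted before, excluded after
  expect_true(res$composite_before[1]); expect_false(res$composite_after[1])
  # a non-seizure basis always survives the exclusion
  expect_true(res$composite_after[2])
  expect_true(res$composite_after[3])
  # no congenital token: untouched
  expect_true(res$composite_after[4])
  expect_equal(res$exclusion_reason[1], "congenital_condition_seizures_only")
})

test_that("without exclusion tokens, before and after composites coincide", {
  cohort <- generate_cohort(small_config(
    seed = 31, exclusion_prob_given_seizure = 0))
  inf <- merge_to_infants(clean_episodes(cohort$episodes)$retained)
  res <- classify_infants(inf, warn_unknown = FALSE)
  expect_identical(res$composite_after, res$composite_before)
})

test_that("stratified counts partition and bound correctly", {
  inf <- random_small_infants(n = 200, max_codes = 3)
  res <- classify_infants(inf, warn_unknown = FALSE)
  counts <- count_cases(res)

  pick <- function(stratum, measure) {
    counts$count[counts$stratum == stratum & counts$measure == measure]
  }
  # composite counts each infant once: bounded by the sum over conditions
  cond_sum <- sum(vapply(condition_flags(), function(m) pick("all", m),
                         numeric(1)))
  expect_lte(pick("all", "composite_before"), cond_sum)
  expect_lte(pick("all", "composite_after"), pick("all", "composite_before"))
  # term + preterm + missing-GA partitions the cohort
  expect_equal(pick("term", "admitted_infants") +
                 pick("preterm", "admitted_infants") +
                 pick("all", "missing_ga"),
               pick("all", "admitted_infants"))
  # subgroup nesting
  expect_lte(pick("lt32", "composite_after"), pick("lt34", "composite_after"))
  expect_lte(pick("lt34", "composite_after"), pick("preterm", "composite_after"))
})

test_that("removing a condition's tokens zeroes it without touching others", {
  inf <- random_small_infants(n = 150, max_codes = 3)
  full <- condition_catalog()
  res_full <- classify_infants(inf, full, warn_unknown = FALSE)

  pruned <- full
  pruned$conditions$stroke$tokens <- "retired_stroke_token"
  res_pruned <- classify_infants(inf, pruned, warn_unknown = FALSE)

  expect_equal(sum(res_pruned$stroke), 0)
  for (cond in setdiff(condition_flags(), "stroke")) {
    expect_identical(res_pruned[[cond]], res_full[[cond]])
  }
})

test_that("catalog YAML round-trips and rejects inconsistent token sets", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_catalog(condition_catalog(), path)
  back <- read_catalog(path)
  expect_identical(back$conditions$cpvl$restriction, "preterm")
  expect_identical(back$exclusions, condition_catalog()$exclusions)

  bad <- condition_catalog()
  bad$conditions$seizures$tokens <- c("seizure_clinical", "congenital_infection")
  expect_error(classify_infants(random_small_infants(2), bad),
               class = "neosurv_catalog_error")
})

test_that("HIE can be restricted to moderate and severe grades", {
  inf <- infants_from(
    list(ga = 40L, codes = "hie_mild"),
    list(ga = 40L, codes = "hie_severe")
  )
  res_all <- classify_infants(inf, condition_catalog(include_mild_hie = TRUE),
                              warn_unknown = FALSE)
  res_ms <- classify_infants(inf, condition_catalog(include_mild_hie = FALSE),
                             warn_unknown = FALSE)
  expect_equal(res_all$hie, c(TRUE, TRUE))
  expect_equal(res_ms$hie, c(FALSE, TRUE))
})
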