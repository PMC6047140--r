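test_that("cohort generation is deterministic and internally consistent", {
  cfg <- small_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$episodes, b$episodes)
  expect_identical(a$truth$infants, b$truth$infants)

  # every admitted infant has at least one episode; multi-episode infants two,
  # with consistent infant-level fields and the code union preserved
  inf <- a$truth$infants
  ep_per_infant <- table(a$episodes$infant_id)
  expect_setequal(names(ep_per_infant), inf$infant_id)
  expect_identical(as.integer(ep_per_infant[inf$infant_id]), inf$n_episodes)

  by_inf <- split(a$episodes, a$episodes$infant_id)
  multi <- inf$infant_id[inf$n_episodes > 1]
  for (id in head(multi, 20)) {
    eps <- by_inf[[id]]
    expect_equal(length(unique(eps$gestational_weeks)), 1)
    expect_equal(length(unique(eps$unit_id)), 1)
  }

  # ground truth composite is the counted-once OR of the condition flags
  flags <- as.matrix(inf[condition_flags()])
  expect_identical(inf$composite_before, rowSums(flags) > 0)
  expect_true(all(inf$composite_after <= inf$composite_before))
})

test_that("zero condition prevalences give a cohort with no cases", {
  cfg <- small_config(seed = 2, condition_prevalences = zero_prevalences())
  cohort <- generate_cohort(cfg)
  expect_equal(sum(cohort$truth$infants$composite_before), 0)
  expect_true(all(cohort$episodes$codes == ""))
})

test_that("generated condition counts match binomial expectation", {
  prev <- default_prevalences()
  prev$term[prev$condition == "seizures"] <- 0.02
  prev$preterm[prev$condition == "seizures"] <- 0.02
  cfg <- cohort_config(n_live_births = 10000, preterm_fraction = 0.07,
                       condition_prevalences = prev, seizure_hie_rr = 1,
                       seed = 3)
  cohort <- generate_cohort(cfg)
  n_adm <- nrow(cohort$truth$infants)
  observed <- sum(cohort$truth$infants$seizures)
  expected <- n_adm * 0.02
  sd3 <- 3 * sqrt(n_adm * 0.02 * 0.98)
  expect_lt(abs(observed - expected), sd3)
})

test_that("cPVL is never generated for term infants", {
  for (seed in 1:5) {
    inf <- generate_cohort(small_config(seed = seed))$truth$infants
    expect_equal(sum(inf$cpvl & inf$stratum == "term"), 0)
  }
})

test_that("invalid configs are rejected naming the offending field", {
  expect_error(cohort_config(preterm_fraction = 1.2), "preterm_fraction",
               class = "neosurv_config_error")
  expect_error(cohort_config(n_live_births = 0), "n_live_births",
               class = "neosurv_config_error")
  prev <- default_prevalences()
  prev$term[prev$condition == "cpvl"] <- 0.01
  expect_error(cohort_config(condition_prevalences = prev), "cpvl",
               class = "neosurv_config_error")
})

test_that("coverage mask keeps exactly the participating units' episodes", {
  cohort <- generate_cohort(small_config(seed = 4))
  units <- unique(cohort$episodes$unit_id)

  expect_identical(apply_coverage_mask(cohort$episodes, units),
                   cohort$episodes)
  expect_error(apply_coverage_mask(cohort$episodes, character(0)),
               class = "neosurv_coverage_error")

  dropped <- units[1]
  masked <- apply_coverage_mask(cohort$episodes, setdiff(units, dropped))
  gone <- cohort$episodes$infant_id[cohort$episodes$unit_id == dropped]
  expect_false(any(masked$infant_id %in% gone))

  # 9 of 10 units under uniform assignment: ~90% of episodes observed
  cfg10 <- small_config(seed = 5, n_units = 10)
  co10 <- generate_cohort(cfg10)
  masked10 <- apply_coverage_mask(co10$episodes, sprintf("U%03d", 1:9))
  n <- nrow(co10$episodes)
  expect_lt(abs(nrow(masked10) - 0.9 * n), 3 * sqrt(n * 0.9 * 0.1))
})

test_that("dirty-record injection tags exactly what it adds", {
  cohort <- generate_cohort(small_config(seed = 6))
  ep <- cohort$episodes

  none <- inject_dirty_records(ep, dup_rate = 0, out_of_range_rate = 0, seed = 1)
  expect_identical(none$episodes, ep)
  expect_equal(nrow(none$injected), 0)

  all_dup <- inject_dirty_records(ep, dup_rate = 1, out_of_range_rate = 0, seed = 1)
  expect_true(all(duplicated(all_dup$episodes) |
                    duplicated(all_dup$episodes, fromLast = TRUE)))

  some <- inject_dirty_records(ep, dup_rate = 0, out_of_range_rate = 0.02, seed = 2)
  n_oor <- nrow(some$injected)
  expect_lt(abs(n_oor - 0.02 * nrow(ep)), 3 * sqrt(nrow(ep) * 0.02 * 0.98))
  bad_ga <- some$injected$defect == "gestation_out_of_range"
  expect_true(all(some$injected$gestational_weeks[bad_ga] > 44))
  inv <- some$injected$defect == "date_inversion"
  expect_true(all(some$injected$discharge_date[inv] <
                    some$injected$admission_date[inv]))
})

test_that("configured prevalences are recovered across seeds", {
  prev <- default_prevalences()
  tot <- setNames(numeric(nrow(prev)), prev$condition)
  n_term <- 0; n_pre <- 0
  tot_term <- tot; tot_pre <- tot
  for (seed in 1:8) {
    inf <- generate_cohort(small_config(seed = seed))$truth$infants
    n_term <- n_term + sum(inf$stratum == "term")
    n_pre <- n_pre + sum(inf$stratum == "preterm")
    for (cond in prev$condition) {
      tot_term[cond] <- tot_term[cond] + sum(inf[[cond]][inf$stratum == "term"])
      tot_pre[cond] <- tot_pre[cond] + sum(inf[[cond]][inf$stratum == "preterm"])
    }
  }
  for (cond in prev$condition) {
    p_t <- prev$term[prev$condition == cond]
    p_p <- prev$preterm[prev$condition == cond]
    expect_lt(abs(tot_term[[cond]] - n_term * p_t),
              4 * sqrt(n_term * p_t * (1 - p_t)) + 1)
    expect_lt(abs(tot_pre[[cond]] - n_pre * p_p),
              4 * sqrt(n_pre * p_p * (1 - p_p)) + 1)
  }
})
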