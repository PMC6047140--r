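test_that("cleaning collapses duplicates and rejects impossible values", {
  ep <- dplyr::bind_rows(
    make_episode("a"),
    make_episode("a"), # exact duplicate
    make_episode("b", ga = 99),
    make_episode("c", admission = "2015-05-10", discharge = "2015-05-01"),
    make_episode("d", ga = 30)
  )
  cleaned <- clean_episodes(ep)
  expect_equal(nrow(cleaned$retained), 2)
  expect_setequal(cleaned$retained$infant_id, c("a", "d"))
  expect_equal(sort(cleaned$rejects$reason),
               c("date_inversion", "duplicate", "gestation_out_of_range"))
  # every input row classified exactly once
  expect_equal(nrow(cleaned$retained) + nrow(cleaned$rejects), nrow(ep))
})

test_that("cleaning a dirty synthetic cohort rejects exactly the injected rows", {
  cohort <- generate_cohort(small_config(seed = 21))
  dirty <- inject_dirty_records(cohort$episodes, dup_rate = 0.03,
                                out_of_range_rate = 0.02, seed = 9)
  cleaned <- clean_episodes(dirty$episodes)

  expect_identical(
    cleaned$retained[order(cleaned$retained$infant_id,
                           cleaned$retained$admission_date), ],
    cohort$episodes
  )
  got <- table(cleaned$rejects$reason)
  want <- table(dirty$injected$defect)
  expect_identical(as.list(got), as.list(want))
  # row-level identity, not just counts
  expect_setequal(
    do.call(paste, cleaned$rejects[episode_columns()]),
    do.call(paste, dirty$injected[episode_columns()])
  )
})

test_that("merging unions codes and keeps one record per infant", {
  ep <- dplyr::bind_rows(
    make_episode("a", admission = "2015-01-10", discharge = "2015-01-15",
                 codes = "seizure_clinical"),
    make_episode("a", admission = "2015-02-01", discharge = "2015-02-03",
                 codes = "hie_moderate;seizure_clinical"),
    make_episode("b", codes = "cystic_pvl", ga = 30)
  )
  inf <- merge_to_infants(ep)
  expect_equal(nrow(inf), 2)
  expect_equal(inf$codes[inf$infant_id == "a"], "hie_moderate;seizure_clinical")
  expect_equal(inf$n_episodes[inf$infant_id == "a"], 2L)
})

test_that("merging single-episode infants is the identity on count", {
  ep <- dplyr::bind_rows(lapply(letters[1:5], make_episode))
  expect_equal(nrow(merge_to_infants(ep)), 5)
})

test_that("merge is idempotent and never loses codes", {
  cohort <- generate_cohort(small_config(seed = 22))
  cleaned <- clean_episodes(cohort$episodes)
  inf <- merge_to_infants(cleaned$retained)

  expect_equal(nrow(inf), nrow(cohort$truth$infants))
  expect_lte(nrow(inf), nrow(cleaned$retained))

  # flatten the merged records back to single-episode form and re-merge
  flattened <- tibble::tibble(
    infant_id = inf$infant_id, unit_id = "U001", year = inf$year,
    admission_date = as.Date("2015-06-01"),
    discharge_date = as.Date("2015-06-02"),
    gestational_weeks = inf$gestational_weeks, codes = inf$codes
  )
  again <- merge_to_infants(clean_episodes(flattened)$retained)
  expect_identical(again[c("infant_id", "year", "gestational_weeks", "codes")],
                   inf[c("infant_id", "year", "gestational_weeks", "codes")])

  # no code present in an infant's episodes is absent from the merged record
  ep_codes <- tapply(cleaned$retained$codes, cleaned$retained$infant_id,
                     function(x) sort(unique(unlist(strsplit(x, ";")))))
  for (id in sample(inf$infant_id, 25)) {
    toks <- setdiff(ep_codes[[id]], "")
    merged <- strsplit(inf$codes[inf$infant_id == id], ";")[[1]]
    expect_true(all(toks %in% merged))
  }
})

test_that("gestational-age conflicts use the earliest episode and are flagged", {
  ep <- dplyr::bind_rows(
    make_episode("a", admission = "2015-01-01", discharge = "2015-01-05", ga = 30),
    make_episode("a", admission = "2015-02-01", discharge = "2015-02-05", ga = 33)
  )
  inf <- merge_to_infants(ep)
  expect_equal(inf$gestational_weeks, 30L)
  conflicts <- attr(inf, "ga_conflicts")
  expect_equal(conflicts$infant_id, "a")
  expect_equal(conflicts$reason, "gestation_inconsistent")

  # one-week discrepancies are tolerated silently
  ep$gestational_weeks[2] <- 31L
  expect_equal(nrow(attr(merge_to_infants(ep), "ga_conflicts")), 0)
})

test_that("episode CSV round-trips and malformed rows are hard errors", {
  cohort <- generate_cohort(cohort_config(n_live_births = 2000, seed = 23))
  path <- withr::local_tempfile(fileext = ".csv")
  write_episodes(cohort$episodes, path)
  back <- read_episodes(path)
  expect_identical(as.data.frame(back), as.data.frame(cohort$episodes))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("infant_id,unit_id,year,admission_date,discharge_date,gestational_weeks,codes",
               "a,U001,2015,2015-01-01,2015-01-02,notanumber,"), bad)
  expect_error(read_episodes(bad), class = "neosurv_parse_error")
})
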