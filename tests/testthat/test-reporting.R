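tiny_pipeline <- function(seed = 1, ...) {
  run_pipeline(pipeline_config(scale = 0.01, ...), seed = seed, quiet = TRUE)
}

test_that("complete years print a CI, adjusted years a range, never both", {
  res <- tiny_pipeline(seed = 41)
  yr <- res$report$years
  adj <- yr[yr$adjusted, ]
  com <- yr[!yr$adjusted, ]
  expect_setequal(adj$year, c(2010, 2011))
  expect_true(all(grepl("^\\d+\\.\\d+ to \\d+\\.\\d+$", adj$rate)))
  expect_true(all(grepl("^\\d+\\.\\d+ \\(\\d+\\.\\d+ to \\d+\\.\\d+\\)$",
                        com$rate)))

  # a year with both an estimate and an adjustment is rejected
  expect_error(
    build_report(res$counts, res$estimates,
                 dplyr::mutate(res$adjustments, year = c(2012L, 2013L)),
                 res$denominators),
    class = "neosurv_report_error"
  )
})

test_that("report rows reconcile exactly with the counts table", {
  res <- tiny_pipeline(seed = 42)
  counts <- res$counts
  for (i in seq_len(nrow(res$report$years))) {
    r <- res$report$years[i, ]
    for (m in c("admitted_infants", "composite_before", "composite_after")) {
      expect_equal(r[[m]],
                   counts$count[counts$year == r$year &
                                  counts$stratum == "all" &
                                  counts$measure == m])
    }
  }
})

test_that("the pipeline is deterministic given a seed", {
  a <- tiny_pipeline(seed = 43)
  b <- tiny_pipeline(seed = 43)
  expect_identical(a$report$years, b$report$years)
  expect_identical(a$counts, b$counts)
  expect_identical(a$adjustments, b$adjustments)
  c <- tiny_pipeline(seed = 44)
  expect_false(identical(a$counts, c$counts))
})

test_that("a zero-prevalence run yields an all-zero report without crashing", {
  res <- run_pipeline(
    pipeline_config(scale = 0.005, dup_rate = 0,
                    out_of_range_rate = 0,
                    base = list(condition_prevalences = zero_prevalences(),
                                exclusion_prob_given_seizure = 0)),
    seed = 45, quiet = TRUE
  )
  expect_true(all(res$report$years$composite_before == 0))
  expect_true(all(res$report$years$composite_after == 0))
  expect_true(all(res$report$conditions$n_all == 0))
})

test_that("report CSVs and printed rendering are produced", {
  res <- tiny_pipeline(seed = 46)
  dir <- withr::local_tempdir()
  write_report(res$report, dir)
  expect_true(file.exists(file.path(dir, "annual_summary.csv")))
  expect_true(file.exists(file.path(dir, "condition_counts.csv")))
  printed <- capture.output(print(res$report))
  expect_true(any(grepl("annual surveillance", printed)))
  expect_equal(sum(grepl("adjusted range", printed)), 2)
})

test_that("tidiers and plots expose the result types", {
  res <- tiny_pipeline(seed = 47)
  expect_s3_class(tidy(res$estimates), "tbl_df")
  expect_s3_class(tidy(res$adjustments), "tbl_df")
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_years, 6)
  p <- autoplot(res$report)
  expect_s3_class(p, "ggplot")
  p2 <- plot_annual_rates(res$estimates, res$adjustments)
  expect_s3_class(p2, "ggplot")
})

test_that("the command-line driver simulates and cleans via CSV files", {
  exe <- system.file("exec", "neosurv", package = "neosurv")
  if (exe == "") {
    exe <- file.path(system.file(package = "neosurv"), "exec", "neosurv")
  }
  skip_if(!file.exists(exe), "exec script not found")
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "cohort.yaml")
  yaml::write_yaml(list(n_live_births = 2000L), cfg)
  out <- file.path(dir, "episodes.csv")
  status <- system2("Rscript", c(exe, "simulate", "--config", cfg,
                                 "--seed", "5", "--out", out),
                    stdout = FALSE, stderr = FALSE, env = libs)
  expect_equal(status, 0)
  ep <- read_episodes(out)
  expect_gt(nrow(ep), 0)

  cleaned_path <- file.path(dir, "retained.csv")
  status <- system2("Rscript", c(exe, "clean", "--in", out, "--out",
                                 cleaned_path, "--log-level", "quiet"),
                    stdout = FALSE, stderr = FALSE, env = libs)
  expect_equal(status, 0)
  expect_equal(nrow(read_episodes(cleaned_path)), nrow(ep))
})
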