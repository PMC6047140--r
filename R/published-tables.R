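#' Published England live-birth denominators, 2010-2015
#'
#' Office for National Statistics live births in England by calendar year and
#' gestational-age stratum, as used for the national brain-injury incidence
#' denominators. Term means >= 37 completed weeks, preterm < 37 weeks.
#'
#' @return A tibble with columns `year`, `stratum` (`"all"`, `"term"`,
#'   `"preterm"`) and `live_births`.
#' @export
#' @examples
#' england_live_births()
england_live_births <- function() {
  tibble(
    year = rep(2010:2015, times = 3),
    stratum = rep(c("all", "term", "preterm"), each = 6),
    live_births = c(
      687007, 688120, 694241, 664517, 661496, 664399,
      627357, 630419, 640787, 612816, 607972, 609076,
      43928, 44547, 49949, 48844, 49379, 50308
    )
  )
}

#' Published annual composite brain-injury counts, 2010-2015
#'
#' Annual neonatal-unit admissions, live births and composite brain-injury
#' case counts for England by gestational-age stratum, as published for the
#' national surveillance series. For 2010-2011 registry coverage was
#' incomplete (roughly 90% of neonatal units contributed), so adjusted
#' lower/upper case-count ranges are given; from 2012 coverage was complete
#' and the adjusted columns are `NA`.
#'
#' @return A tibble with one row per (year, stratum): `admissions`,
#'   `live_births`, `cases_before` and `cases_after` (composite counts before
#'   and after exclusion of seizure-only infants with congenital conditions),
#'   `n_excluded`, and `adjusted_*` range columns for incomplete-coverage
#'   years.
#' @export
nnrd_annual_counts <- function() {
  all <- tibble(
    year = 2010:2015, stratum = "all",
    admissions = c(64375, 72678, 78952, 80199, 84981, 88785),
    cases_before = c(3011, 3377, 3404, 3393, 3558, 3445),
    n_excluded = c(45, 46, 45, 35, 30, 27),
    cases_after = c(2966, 3331, 3359, 3358, 3528, 3418),
    adjusted_before_low = c(3160, 3434, NA, NA, NA, NA),
    adjusted_before_high = c(3619, 3630, NA, NA, NA, NA),
    adjusted_after_low = c(3113, 3387, NA, NA, NA, NA),
    adjusted_after_high = c(3566, 3581, NA, NA, NA, NA)
  )
  term <- tibble(
    year = 2010:2015, stratum = "term",
    admissions = c(35415, 41429, 46200, 47935, 51945, 55045),
    cases_before = c(1830, 2126, 2109, 2130, 2215, 2136),
    n_excluded = NA_real_,
    cases_after = c(NA, NA, 2074, 2105, 2189, 2116),
    adjusted_before_low = c(1979, 2213, NA, NA, NA, NA),
    adjusted_before_high = c(2218, 2285, NA, NA, NA, NA),
    adjusted_after_low = c(1949, 2179, NA, NA, NA, NA),
    adjusted_after_high = c(2186, 2249, NA, NA, NA, NA)
  )
  preterm <- tibble(
    year = 2010:2015, stratum = "preterm",
    admissions = c(28960, 31249, 32752, 32264, 33036, 33740),
    cases_before = c(1181, 1251, 1295, 1263, 1343, 1309),
    n_excluded = NA_real_,
    cases_after = c(NA, NA, 1285, 1253, 1339, 1302),
    adjusted_before_low = c(1273, 1281, NA, NA, NA, NA),
    adjusted_before_high = c(1310, 1298, NA, NA, NA, NA),
    adjusted_after_low = c(1254, 1268, NA, NA, NA, NA),
    adjusted_after_high = c(1290, 1284, NA, NA, NA, NA)
  )
  out <- bind_rows(all, term, preterm)
  left_join(out, england_live_births(), by = c("year", "stratum")) |>
    relocate("live_births", .after = "admissions")
}

#' Published per-condition case counts, 2012-2015
#'
#' Annual case counts for the individual conditions of the composite
#' brain-injury definition, for the complete-coverage years. An infant can be
#' a case for several conditions, so per-condition counts do not sum to the
#' composite count. `n_severe_pivh_lt32` is severe (grade 3-4)
#' periventricular/intraventricular haemorrhage among infants born before 32
#' weeks; `n_cpvl_lt34` is cystic periventricular leucomalacia among infants
#' born before 34 weeks.
#'
#' @return A tibble with columns `condition`, `year`, `n_all`, `n_term`,
#'   `n_preterm`, `n_severe_pivh_lt32`, `n_cpvl_lt34`.
#' @export
brain_injury_condition_counts <- function() {
  tribble(
    ~condition, ~year, ~n_all, ~n_term, ~n_preterm,
    "seizures", 2012, 1445, 1065, 378,
    "seizures", 2013, 1432, 1036, 396,
    "seizures", 2014, 1360, 1009, 351,
    "seizures", 2015, 1249, 919, 330,
    "intracranial_haemorrhage", 2012, 754, 110, 644,
    "intracranial_haemorrhage", 2013, 677, 94, 583,
    "intracranial_haemorrhage", 2014, 689, 104, 585,
    "intracranial_haemorrhage", 2015, 726, 117, 609,
    "stroke", 2012, 77, 64, 13,
    "stroke", 2013, 100, 78, 22,
    "stroke", 2014, 88, 72, 16,
    "stroke", 2015, 90, 76, 14,
    "hie", 2012, 1674, 1409, 265,
    "hie", 2013, 1674, 1401, 273,
    "hie", 2014, 1824, 1480, 344,
    "hie", 2015, 1742, 1417, 325,
    "cns_infection", 2012, 353, 188, 165,
    "cns_infection", 2013, 422, 266, 156,
    "cns_infection", 2014, 504, 284, 220,
    "cns_infection", 2015, 465, 277, 188,
    "bilirubin_encephalopathy", 2012, 8, 6, 2,
    "bilirubin_encephalopathy", 2013, 7, 5, 2,
    "bilirubin_encephalopathy", 2014, 2, 2, 0,
    "bilirubin_encephalopathy", 2015, 4, 4, 0,
    "cpvl", 2012, 199, NA, 199,
    "cpvl", 2013, 175, NA, 175,
    "cpvl", 2014, 171, NA, 171,
    "cpvl", 2015, 184, NA, 184
  ) |>
    left_join(
      tribble(
        ~condition, ~year, ~n_severe_pivh_lt32, ~n_cpvl_lt34,
        "intracranial_haemorrhage", 2012, 483, NA,
        "intracranial_haemorrhage", 2013, 445, NA,
        "intracranial_haemorrhage", 2014, 468, NA,
        "intracranial_haemorrhage", 2015, 452, NA,
        "cpvl", 2012, NA, 186,
        "cpvl", 2013, NA, 175,
        "cpvl", 2014, NA, 157,
        "cpvl", 2015, NA, 176
      ),
      by = c("condition", "year")
    )
}

#' Published rate rows with printed numerator and denominator
#'
#' Every incidence rate and 95% CI of the published surveillance tables whose
#' numerator and denominator are both printed, together with the published
#' text. Used as a regression fixture: recomputing each row with
#' [rate_estimate()] should reproduce the printed values after rounding.
#' Severe P/IVH (<32 weeks) and cPVL (<34 weeks) rates are omitted because
#' their gestational-age-specific denominators are not published.
#'
#' @return A tibble with columns `table`, `year`, `measure`, `stratum`,
#'   `numerator`, `denominator`, `scale`, `digits`, `printed`.
#' @export
published_rates <- function() {
  counts <- nnrd_annual_counts()
  d_all <- counts |> filter(.data$stratum == "all", .data$year >= 2012)
  d_term <- counts |> filter(.data$stratum == "term", .data$year >= 2012)
  d_pre <- counts |> filter(.data$stratum == "preterm", .data$year >= 2012)

  composite <- bind_rows(
    tibble(
      table = "annual_all", year = 2012:2015, measure = "composite_before",
      stratum = "all", numerator = d_all$cases_before,
      denominator = d_all$live_births, scale = 1e3, digits = 2,
      printed = c("4.90 (4.47 to 5.07)", "5.11 (4.94 to 5.28)",
                  "5.38 (5.20 to 5.56)", "5.19 (5.01 to 5.36)")
    ),
    tibble(
      table = "annual_all", year = 2012:2015, measure = "composite_after",
      stratum = "all", numerator = d_all$cases_after,
      denominator = d_all$live_births, scale = 1e3, digits = 2,
      printed = c("4.84 (4.68 to 5.00)", "5.05 (4.89 to 5.23)",
                  "5.33 (5.16 to 5.51)", "5.14 (4.97 to 5.32)")
    ),
    tibble(
      table = "annual_term", year = 2012:2015, measure = "composite_after",
      stratum = "term", numerator = d_term$cases_after,
      denominator = d_term$live_births, scale = 1e3, digits = 2,
      printed = c("3.24 (3.10 to 3.38)", "3.43 (3.29 to 3.58)",
                  "3.60 (3.45 to 3.75)", "3.47 (3.33 to 3.62)")
    ),
    tibble(
      table = "annual_preterm", year = 2012:2015, measure = "composite_after",
      stratum = "preterm", numerator = d_pre$cases_after,
      denominator = d_pre$live_births, scale = 1e3, digits = 2,
      printed = c("25.73 (24.36 to 27.17)", "25.65 (24.27 to 27.11)",
                  "27.12 (25.70 to 28.61)", "25.88 (24.51 to 27.33)")
    )
  )

  cond <- brain_injury_condition_counts()
  cond_all <- function(condition, scale, digits, printed) {
    n <- cond$n_all[cond$condition == condition]
    tibble(
      table = "conditions", year = 2012:2015, measure = condition,
      stratum = "all", numerator = n, denominator = d_all$live_births,
      scale = scale, digits = digits, printed = printed
    )
  }
  conditions <- bind_rows(
    cond_all("seizures", 1e3, 1,
             c("2.1 (2.0 to 2.1)", "2.2 (2.1 to 2.3)",
               "2.1 (2.0 to 2.2)", "1.9 (1.8 to 2.0)")),
    cond_all("intracranial_haemorrhage", 1e3, 1,
             c("1.1 (1.0 to 1.2)", "1.0 (0.9 to 1.1)",
               "1.0 (1.0 to 1.1)", "1.1 (1.0 to 1.2)")),
    tibble(
      table = "conditions", year = 2012:2015,
      measure = "intracranial_haemorrhage", stratum = "term",
      numerator = cond$n_term[cond$condition == "intracranial_haemorrhage"],
      denominator = d_term$live_births, scale = 1e4, digits = 1,
      printed = c("1.7 (1.4 to 2.1)", "1.5 (1.3 to 1.9)",
                  "1.7 (1.4 to 2.1)", "1.9 (1.6 to 2.3)")
    ),
    cond_all("stroke", 1e3, 2,
             c("0.11 (0.09 to 0.14)", "0.15 (0.12 to 0.18)",
               "0.13 (0.11 to 0.16)", "0.14 (0.11 to 0.17)")),
    cond_all("hie", 1e3, 1,
             c("2.4 (2.3 to 2.5)", "2.5 (2.4 to 2.6)",
               "2.8 (2.6 to 2.9)", "2.6 (2.5 to 2.8)")),
    cond_all("cns_infection", 1e3, 2,
             c("0.51 (0.46 to 0.56)", "0.64 (0.58 to 0.70)",
               "0.76 (0.70 to 0.83)", "0.70 (0.64 to 0.77)")),
    cond_all("bilirubin_encephalopathy", 1e5, 1,
             c("1.2 (0.6 to 2.3)", "1.1 (0.5 to 2.2)",
               "0.3 (0.1 to 1.2)", "0.6 (0.2 to 1.6)")),
    cond_all("cpvl", 1e3, 1,
             c("0.3 (0.3 to 0.3)", "0.3 (0.2 to 0.3)",
               "0.3 (0.2 to 0.3)", "0.3 (0.2 to 0.3)"))
  )

  bind_rows(composite, conditions)
}

#' Published adjusted rate ranges for incomplete-coverage years
#'
#' The 2010-2011 adjusted case-count ranges with their live-birth
#' denominators and the printed rate ranges per 1000 live births.
#'
#' @return A tibble with columns `year`, `stratum`, `phase`
#'   (`"before"`/`"after"` exclusions), `cases_low`, `cases_high`,
#'   `denominator`, `digits`, `printed`.
#' @export
published_adjusted_ranges <- function() {
  tribble(
    ~year, ~stratum, ~phase, ~cases_low, ~cases_high, ~denominator, ~printed,
    2010, "all", "before", 3160, 3619, 687007, "4.60 to 5.27",
    2010, "all", "after", 3113, 3566, 687007, "4.53 to 5.19",
    2011, "all", "before", 3434, 3630, 688120, "4.99 to 5.28",
    2011, "all", "after", 3387, 3581, 688120, "4.93 to 5.20",
    2010, "term", "after", 1949, 2186, 627357, "3.11 to 3.48",
    2011, "term", "after", 2179, 2249, 630419, "3.46 to 3.57",
    2010, "preterm", "after", 1254, 1290, 43928, "28.54 to 29.37",
    2011, "preterm", "after", 1268, 1284, 44547, "28.47 to 28.83"
  ) |>
    mutate(digits = 2L)
}
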