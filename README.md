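# neosurv

National surveillance of brain injuries occurring at or soon after birth,
from routinely recorded neonatal-unit electronic patient records.

Neonatal brain injury — seizures, intracranial haemorrhage, perinatal
stroke, hypoxic-ischaemic encephalopathy (HIE), central nervous system
infection, bilirubin encephalopathy and, in preterm infants, cystic
periventricular leucomalacia (cPVL) — is a leading cause of neonatal death
and lifelong disability, and reducing it is a standing target of national
maternity policy. `neosurv` implements the full analysis pipeline that turns
episode-level registry records into annual population incidence figures:

* **composite case ascertainment** — a configurable condition catalog maps
  raw diagnosis codes to the seven conditions; an infant with any qualifying
  condition is counted **once**, with cPVL restricted to infants born
  <37 completed weeks, and composite counts reported before and after
  excluding seizure-only cases carrying congenital diagnoses (injury of
  antenatal origin);
* **record preparation** — episode cleaning (duplicates, out-of-range
  gestations, inverted date intervals, each rejected with a machine-readable
  reason) and merging to a single record per infant with code-set union;
* **incidence estimation** — for case count $n$ and live births $d$, the
  rate per $s$ live births is $n/d \times s$ with the log-transformed
  Poisson 95% CI $n\,e^{\pm 1.96/\sqrt{n}}/d \times s$ (exact Poisson upper
  bound $3.6889/d \times s$ when $n = 0$), stratified by gestational age
  (term ≥37 weeks, preterm <37, plus <32 and <34 subgroups);
* **coverage adjustment** — for years when ~10% of neonatal units did not
  contribute records, a lower/upper range: observed admissions inflated by
  the extreme complete-year growth ratios, the case/admission proportion
  widened by ±2 SDs of the complete-year proportions;
* **synthetic cohorts** — a seeded generator emulating the registry's
  structure (multiple episodes per infant, stratified admission and
  condition prevalences calibrated to the published 2015 England cohort,
  unit-level non-participation, injected data defects) with exact ground
  truth, so the whole pipeline is testable without confidential data.

The package is tidyverse-native: tibbles in and out, `tidy()`/`glance()`
methods, `autoplot()` for the result types, and a thin `exec/neosurv`
command-line driver (`simulate`, `clean`, `ascertain`, `rates`, `adjust`,
`report`).

## Worked example

The published 2015 England figures — 3418 composite cases after exclusions
among 664 399 live births — reproduce directly:

```r
library(neosurv)
est <- rate_estimate(3418, 664399, scale = 1000)
est
#> # A tibble: 1 × 7
#>   numerator denominator scale  rate ci_low ci_high method
#>       <dbl>       <dbl> <dbl> <dbl>  <dbl>   <dbl> <chr>
#> 1      3418      664399  1000  5.14   4.97    5.32 poisson_log
format_rate(est, 2)
#> [1] "5.14 (4.97 to 5.32)"
```

i.e. 5.14 brain injuries per 1000 live births (95% CI 4.97 to 5.32): about
1 in 195 live-born infants. The same call on the stratum counts gives 3.47
(3.33 to 3.63) per 1000 term births and 25.88 (24.51 to 27.33) per 1000
preterm births — preterm infants carry roughly seven times the risk.

A full synthetic surveillance run, 2010–2015 at 3% of national scale with
incomplete coverage in 2010–2011:

```r
res <- run_pipeline(pipeline_config(scale = 0.03), seed = 7, quiet = TRUE)
res
#> Brain injuries occurring at or soon after birth: annual surveillance
#> --------------------------------------------------------------------
#>  year   admitted  live births   before  excluded    after rate/1000 live births
#>  2010      1 810       20 610      105         0      105 5.09 to 6.84 (adjusted range)
#>  2011      1 937       20 644      108         0      108 5.23 to 7.07 (adjusted range)
#>  2012      2 363       20 827      118         1      117 5.62 (4.69 to 6.73)
#>  2013      2 369       19 936      135         1      134 6.72 (5.67 to 7.96)
#>  2014      2 605       19 845      132         1      131 6.60 (5.56 to 7.83)
#>  2015      2 674       19 932      110         0      110 5.52 (4.58 to 6.65)
```

Complete-coverage years print a rate with a 95% CI; incomplete-coverage
years print the adjusted range instead — never both. `res$counts` holds the
stratified count table, `res$adjustments` the adjustment details,
`glance(res)` a one-row summary, and `autoplot(res$report)` the annual rate
plot.

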