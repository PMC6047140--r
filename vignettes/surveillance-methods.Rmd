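---
title: "Methods: composite neonatal brain-injury surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite neonatal brain-injury surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neosurv)
```

## The surveillance problem

`neosurv` estimates the annual population incidence of brain injuries
occurring at or soon after birth from routinely recorded neonatal-unit
electronic patient records. A case is an admitted infant with at least one of
seven conditions — neonatal seizures, intracranial haemorrhage, perinatal
stroke, hypoxic-ischaemic encephalopathy (HIE), central nervous system
infection, bilirubin encephalopathy (kernicterus), or, among preterm infants
only, cystic periventricular leucomalacia (cPVL) — detected during the
neonatal-unit stay. The denominator is all live births in the population
year, not admissions: live births are the population at risk, and only a
minority of them are admitted for neonatal care.

Three counting rules matter and are enforced throughout:

1. **Counted once.** An infant with several qualifying conditions is a single
   composite case. Per-condition tables count the same infant once per
   condition, so condition counts do not sum to the composite count.
2. **Population restriction.** cPVL contributes only for infants born before
   37 completed weeks; a cPVL code on a term infant's record never creates a
   case.
3. **Congenital exclusion.** Composite counts are reported before and after
   removing infants whose *only* qualifying condition is seizures and whose
   record also carries a congenital condition indicating injury of antenatal
   origin (congenital encephalopathy including inborn errors of metabolism,
   congenital infection, congenital brain abnormality). An infant qualifying
   through any non-seizure condition is never excluded.

The package is organised as a tidyverse-style pipeline: episode tibbles in,
result tibbles out, with `tidy()`/`glance()` methods and `autoplot()` for the
result types.

## Record preparation

Registry data arrive as care *episodes* — an infant transferred or re-admitted
has several rows. `clean_episodes()` applies the cleaning categories that
registry preparation describes: exact duplicates are collapsed to one copy,
gestational ages outside 22–44 completed weeks are rejected
(`gestation_out_of_range`), and discharge dates before admission are rejected
(`date_inversion`). Every input row is classified exactly once, and rejects
carry machine-readable reasons so cleaning is auditable.

`merge_to_infants()` then builds the unit of ascertainment, one record per
infant: diagnosis codes are unioned across retained episodes, and the cohort
year and gestational age come from the earliest admission — the episode
closest to birth, which is the natural choice when the true assignment rule
is unpublished. Gestational ages differing by more than one completed week
across an infant's episodes are flagged as inconsistencies (the
`ga_conflicts` attribute) while the earliest value is used. Merging is
idempotent, so re-running preparation on prepared data is a no-op.

Near-duplicates (same infant, same unit, overlapping dates) are treated as
legitimate distinct episodes rather than rejected: the registry's real fuzzy
rules are unpublished, and union semantics make redundant codes harmless.

## Case ascertainment

`classify_infants()` intersects each infant's code set with a configurable
`condition_catalog()`. The catalog ships a stand-in vocabulary (the
registry's proprietary item codes are not public) with the structural
features that matter: pairwise-disjoint inclusion token sets, a disjoint
exclusion set, a severe subset of intracranial haemorrhage (grade 3–4
intraventricular/periventricular haemorrhage) for the severe P/IVH tally,
and a severity attribute on HIE tokens. Whether mild HIE counts is a genuine
open question in this surveillance definition — the composite names HIE
unqualified, while condition-level comparisons are usually made for moderate
and severe HIE — so it is a catalog option (`include_mild_hie`), defaulting
to inclusive, not a hard-coded answer. Similarly, the congenital exclusion
is applied strictly to seizure-only cases, the narrow reading of the
definition; widening it to other conditions would be a different definition.

Unknown codes are ignored with a logged warning: national surveillance must
tolerate local coding drift without crashing.

`count_cases()` tallies composite (before/after exclusions) and
per-condition counts for the reporting strata: all infants, term (≥37
weeks), preterm (<37 weeks), and the <32 and <34 week subgroups. Infants
with missing gestational age stay in `all` and are reported under
`missing_ga`, so term + preterm + missing always reconciles with the total.

## Incidence rates and confidence intervals

`rate_estimate(n, d, scale)` returns `n/d × scale` with a 95% CI from the
log-transformed Poisson method:

$$\left[\; \frac{n\,e^{-1.96/\sqrt{n}}}{d} \times s,\;\;
\frac{n\,e^{+1.96/\sqrt{n}}}{d} \times s \;\right]$$

For `n = 0` the lower bound is 0 and the upper bound is the exact Poisson
limit `3.6889/d × s`. The method choice is empirical: recomputing every
published rate whose numerator and denominator are both printed, this
interval reproduces the published tables (e.g. the 2015 preterm CI
24.51–27.33, where a plain Wald interval gives 24.48–27.29), and it tracks
the exact Poisson interval within 2% per bound for counts of 100 or more.
A handful of printed bounds are internally inconsistent in the source tables
(one is a digit transposition; one matches a Wald interval while every
neighbouring row matches the log interval; one row reproduces only with the
adjacent year's denominator); the regression suite records the computed
values for these and documents the discrepancy rather than chasing them.

Rounding is half away from zero (`round_half_up()`) to the decimal places of
each published table — 2 dp for the composite tables, 1–2 dp per condition
row — because `round()`'s round-half-to-even would disagree with the
published rendering.

Denominators are always an input table (`year`, `stratum`, `live_births`),
never derived from the cohort: admitted infants are a subset of live births,
so a cohort-derived denominator would be biased several-fold.

## Adjustment for years with incomplete registry coverage

In early years only about 90% of neonatal units contributed records, so
observed admissions undercount the nation and single-point rates would be
misleading. `adjust_incomplete_year()` produces a range instead:

* **Admissions.** The observed admissions of the incomplete year are
  inflated by the least and most extreme year-over-year growth ratios seen
  across the complete-coverage years (`yearly_increase_bounds()`), on the
  assumption that growth in the unobserved years was no more extreme.
* **Proportion.** The case/admission proportion observed in the incomplete
  year is widened by ±2 sample SDs of the complete-year proportions
  (`proportion_sd()`). The SD is of the proportion of cases to admissions,
  not of the rate per live birth.
* **Counts and rates.** Lower/upper adjusted counts are the products,
  rounded to the nearest integer; rates divide by total live births (per
  1000), assuming the case rate among infants in non-participating units
  equals the observed rate.

The verbal description this implements is directionally ambiguous, and the
published adjusted counts cannot be reproduced arithmetically from the prose
alone; the published range is therefore used to validate the rate-division
step, while the procedure itself is validated by a simulation coverage
study (below). Two guards keep the estimate coherent as a range: inflation
factors are floored at 1, and the lower adjusted count is floored at the
observed count — units missing from the registry can only add cases, never
remove them. Both floors preserve the monotonicity of the range width in
the SD and in the inflation spread.

## The synthetic cohort generator

`generate_cohort()` produces episode-level records with known ground truth
so every downstream stage is testable without access to confidential
records. Its defaults *are* the study conditions of the published 2015
England cohort:

| parameter | default | source |
|---|---|---|
| live births | 664 399 | published 2015 denominator |
| preterm fraction | 50 308 / 664 399 ≈ 7.6% | published stratum denominators |
| admission probability, term | 55 045 / 609 076 ≈ 9.0% | published admissions/births |
| admission probability, preterm | 33 740 / 50 308 ≈ 67% | published admissions/births |
| condition prevalences | per-condition 2015 cases / stratum admissions | published condition counts |
| exclusion codes among seizure cases | 2.5% | published exclusions (27–46/yr) vs seizure cases (~1250–1450/yr) |
| multi-episode probability | 0.3 | plausible transfer/re-admission share; no published figure |
| neonatal units | 160 | order of the English unit count; no published figure |

Conditions are independent Bernoulli draws per admitted infant within
stratum, except one deliberate co-occurrence: seizures are drawn with a
configurable relative risk given HIE (default 5), solved so the marginal
seizure prevalence is preserved. This exercises the counted-once logic
without disturbing prevalence recovery. cPVL is structurally zero for term
infants. Gestational age is integer completed weeks — term uniform on
37–41, preterm from a fixed categorical on 23–36 weighted toward 32–36 so
the <32/<34 subgroups are populated at plausible admitted-cohort shares.
Infants are assigned uniformly to units and keep one unit across episodes;
multi-episode infants have their codes distributed across two episodes
(each code to the first, second or both), so union-merging is genuinely
exercised.

The multi-year driver (`pipeline_config()` + `run_pipeline()`) layers on
the published per-year live births, admission growth (complete-year ratios,
back-extrapolated at their mean growth for the incomplete years) and a
per-year prevalence drift following the published cases/admissions
proportions. The drift matters: the adjustment's SD step measures secular
variation in the proportion, and a generator with constant prevalence would
understate it. Incomplete years mask a seeded 10% of units
(`apply_coverage_mask()`), and `inject_dirty_records()` adds exact
duplicates and impossible values (gestational age 99, inverted dates) at
small rates with a sidecar listing exactly what was injected.

What the generator does **not** emulate: unit-size heterogeneity, transfers
between units, clinically correlated condition clusters beyond the single
seizure–HIE term, within-year seasonality, mortality, or coding error other
than the injected defect classes. One visible consequence: real infants are
more multimorbid than (near-)independent draws, so with every per-condition
prevalence calibrated to the published counts the synthetic *composite*
rate comes out around 6.4 per 1000 live births, above the published
composite of ≈5.1 — the published composite embodies stronger condition
overlap than the single co-occurrence term reproduces. Per-condition rates
match their published counterparts; the composite is structurally an upper
version of it. Passing tests therefore demonstrate the *pipeline's*
correctness on registry-shaped data, not the realism of any particular
clinical trajectory.

## Numerical choices and problem sizes

* Probabilities are validated to [0, 1] with errors naming the offending
  field; configs are immutable value objects.
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  so cohorts, pipelines and reports are bit-reproducible; per-year and
  per-stage seeds are derived from the master seed with fixed prime offsets.
* Duplicate detection is exact equality on all fields; the first occurrence
  is kept.
* Rate errors (zero denominator, numerator above denominator) are hard
  errors, not NaNs.
* The test suite runs cohorts of 10⁴–2×10⁴ live births (≈1300–2700 admitted
  infants) per cohort-year, 20 seeds for prevalence recovery, and 100
  replicates at 3% of national scale for the adjustment coverage study —
  sizes chosen so the whole suite exercises every stage at meaningful counts
  while remaining comfortable on a single CPU. At these sizes the observed
  adjustment-range coverage of the true complete-cohort count is 97–99%.

## Known limitations

* The condition vocabulary is a stand-in; real deployments must supply a
  catalog mapping their local codes.
* The adjustment range is an ad hoc estimator, not a missing-data model; it
  has no formal coverage guarantee, only the simulation evidence above, and
  deliberately errs toward over-covering on the upper side.
* Composite counts at national scale depend on real-world coding behaviour
  (e.g. under-diagnosis of neonatal seizures) that no generator parameter
  captures.
* lt32/lt34 rates require gestational-age-specific live-birth denominators,
  which must be supplied; the shipped England denominator table carries
  all/term/preterm only.
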