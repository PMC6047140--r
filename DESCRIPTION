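Package: neosurv
Title: National Surveillance of Brain Injuries Occurring at or Soon After Birth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population surveillance of neonatal brain injury from
    routinely recorded neonatal-unit electronic patient records. Implements a
    composite expert-consensus case definition (seizures, intracranial
    haemorrhage, perinatal stroke, hypoxic-ischaemic encephalopathy, central
    nervous system infection, bilirubin encephalopathy, and cystic
    periventricular leucomalacia in preterm infants only), episode-level record
    cleaning and merging to one record per infant, stratified incidence rates
    per live birth with log-transformed Poisson confidence intervals, and a
    range adjustment for calendar years with incomplete neonatal-unit registry
    coverage. Ships a synthetic cohort generator with known ground truth so the
    whole pipeline is testable without access to confidential records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
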