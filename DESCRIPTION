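Package: natalink
Title: Maternal-Infant Linkage of Vital Records to Hospital Discharge Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links birth and fetal-death certificate records to hospital
    discharge, emergency department and ambulatory surgery episodes for the
    birthing person and the infant using a multi-pass blocking strategy with
    an additive link score, required-variable rules and score cutoffs.
    Includes ICD-9/ICD-10 prefix code sets for the clinical indicators used
    by the comparators, a ground-truthed synthetic cohort generator with a
    configurable error and missingness model, longitudinal episode linkage
    via encrypted SSNs, and evaluation tables for linkage rates, linked
    versus unlinked populations, dual-source ascertainment, prevalence
    contrasts and truth-based precision and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    lubridate,
    yaml,
    jsonlite,
    ggplot2,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
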