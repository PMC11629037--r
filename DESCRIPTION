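Package: phenoval
Title: Rules-Based Computable Phenotypes for Vaccine Adverse-Event Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and validates postvaccination adverse events of special
    interest (myocarditis/pericarditis after COVID-19 vaccination) in FHIR R4
    electronic health record extracts. Implements a rules-based computable
    phenotype with risk-window and clean-window temporal logic, inpatient
    care-setting and supporting-evidence filters, exchange-style case
    retrieval with demographic multi-match exclusion, two-reviewer
    adjudication bookkeeping with third-reviewer tie-breaking, and the
    validation statistics used in chart-review studies: positive predictive
    value with Agresti-Coull confidence intervals, Cohen kappa interrater
    agreement, and two-sample proportion comparison. Ships a seeded synthetic
    EHR cohort generator with latent truth labels so every pipeline stage is
    testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
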