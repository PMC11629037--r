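# phenoval

Rules-based computable phenotypes for postvaccination adverse-event
surveillance, with the full validation workflow used in chart-review
studies.

## What it is for

Active surveillance of vaccine safety increasingly relies on *computable
phenotypes*: machine-executable rule sets applied to electronic health
record (EHR) data that flag patients with a suspected adverse event of
special interest (AESI) — here, myocarditis/pericarditis after COVID-19
vaccination. Flagged cases are pulled through a health-information
exchange, reviewed by two clinicians, and the algorithm's positive
predictive value (PPV) is estimated from the adjudicated labels.

`phenoval` implements that whole chain for FHIR R4 NDJSON extracts:

1. **Detection** (`detect()`): ordered filter stages with CONSORT-style
   attrition accounting — study-period and care-setting filters (inpatient
   by default), target-diagnosis value-set matching (admitting diagnoses
   ignored), a supporting-evidence requirement (±7 days around the index
   diagnosis), a 365-day *clean window* that must be free of the same
   diagnosis (so cases are incident), and a vaccine-exposure requirement:
   the diagnosis must fall in a **risk window of 0–42 days** after a
   qualifying vaccination. With offset
   `Δ = onset − administration`, a dose qualifies iff `0 ≤ Δ ≤ 42`, and the
   most recent in-window dose (smallest Δ) is retained.
2. **Retrieval** (`retrieve_all()`): exchange-style demographic matching on
   (normalized name, birth date, sex); cases matching multiple registry
   patients are withheld for privacy (*multi-match exclusion*); per-case
   payloads are assembled with per-resource-type date windows
   (observations/diagnostic reports/document references clipped to the
   study period; conditions, encounters, immunizations et al. full
   history; locations/practitioners/medications only when referenced).
3. **Adjudication** (`resolve()`, `adjudicate_all()`): two independent
   reviewers label each case definite/probable/possible/doubtful or
   insufficient-evidence; disagreements go to a third reviewer whose label
   is final. A truth-driven simulator (`simulate_reviews()`) stands in for
   clinicians on synthetic data.
4. **Statistics** (`ppv()`, `agresti_coull_ci()`, `cohen_kappa()`,
   `two_sample_proportion_test()`, `build_report()`):

   - `PPV = TP / (TP + FP)` with `TP = definite + probable`,
     `FP = possible + doubtful`; the alternate convention counts
     insufficient-evidence cases in the denominator.
   - Agresti–Coull 95% CI: `ñ = n + z²`, `p̃ = (x + z²/2)/ñ`,
     `p̃ ± z·√(p̃(1−p̃)/ñ)`, clamped to [0, 1].
   - Cohen `κ = (p_o − p_e)/(1 − p_e)` between the two primary reviewers.
   - Pooled two-sample z test for comparing PPVs across sites.

A seeded synthetic cohort generator (`generate_cohort()`) plants patients
of every structural category — in-window incident cases, out-of-window,
prevalent, outpatient-only, unvaccinated, demographic duplicates,
background — with latent truth labels, so every stage is testable end to
end without any patient data.

## Worked example

```r
library(phenoval)

sc  <- consort_scenario()             # deterministic synthetic study
res <- run_pipeline(sc$bundle, sc$truth)
res$attrition
#>   stage                unit       entering surviving
#> 1 study_period         encounters      194       148
#> 2 care_setting         encounters      148        58
#> 3 target_diagnosis     cases            64        42
#> 4 supporting_evidence  cases            42        42
#> 5 clean_window         cases            42        38
#> 6 vaccine_exposure     cases            38        30
#> 7 one_case_per_patient patients         30        30
#> 8 retrieval_match      cases            30        26
res$report
#> Validation sample results
#>   Definite, n                          3
#>   Probable, n                          11
#>   Possible, n                          0
#>   Doubtful, n                          10
#>   True positives (definite+probable)   14
#>   False positives (possible+doubtful)  10
#>   Cases with sufficient evidence, n    24
#>   PPV, % (95% CI)                      58.3 (38.8-75.6)
#>   Insufficient evidence, n             2
#>   Total cases, n                       26
#>   Insufficient evidence, %             7.7
#>   PPV alternate, % (95% CI)            53.8 (35.5-71.3)
#>   Interrater Cohen kappa               1.000
```

Reading the output: 194 synthetic encounters enter the algorithm; 30
patients survive all seven detection stages; 4 are withheld at retrieval
because their demographics match two registry patients; of the 26
retrieved, 2 lack the documentation needed for a determination, and the 24
adjudicated cases split 14 true / 10 false positives, a PPV of 58.3%
(Agresti–Coull 95% CI 38.8–75.6).

A shell entry point wrapping the same functions ships in
`inst/cli/phenoval-cli.R` (subcommands `generate`, `detect`, `run-all`).

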