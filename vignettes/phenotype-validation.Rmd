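---
title: "Methods: detecting and validating postvaccination myocarditis/pericarditis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and validating postvaccination myocarditis/pericarditis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoval)
```

## The surveillance problem

Myocarditis and pericarditis are rare but clinically significant adverse
events of special interest (AESIs) after mRNA COVID-19 vaccination. Active
surveillance over EHR data needs three things: a *computable phenotype*
that flags suspected cases automatically, a retrieval mechanism that
assembles each flagged case's clinical record for review, and a validation
layer that quantifies how often the algorithm is right. `phenoval`
implements all three, plus a synthetic cohort generator that provides
ground truth for testing.

The package assumes day-granularity dates throughout (timestamps are
truncated on ingest) because every temporal rule in the phenotype —
risk window, clean window, evidence window — is expressed in whole days.

## The detection model

A patient is flagged when there exists a condition record satisfying, in
order:

1. **Study period.** Its encounter starts inside the configured study
   period (default 2020-12-14, the start of COVID-19 vaccine emergency use
   authorization, through 2023-04-28). Encounters are anchored on their
   admission date.
2. **Care setting.** The encounter's setting is in the allowed set
   (default inpatient only; myocarditis/pericarditis severe enough to be
   vaccine-attributable is expected to present in inpatient care, and
   restricting the setting suppresses rule-out and follow-up coding noise).
3. **Target diagnosis.** The condition's coding is in the
   `target_diagnosis` value set, and its diagnosis role is not
   *admitting* (admitting diagnoses are provisional; only confirmed
   diagnoses may anchor a case). The *index date* is the condition's onset
   date; among multiple qualifying conditions the earliest onset wins,
   with ties broken on condition id for determinism.
4. **Supporting evidence.** At least one `supporting_evidence`
   observation (troponin or other cardiac workup) within ±7 days of the
   index date. The window is configurable; ±7 days covers the inpatient
   stay around an acute presentation without reaching into unrelated care.
5. **Clean window.** No target-valueset condition with onset in the
   half-open interval `[index − 365 d, index)`. The index day itself is
   not disqualifying — an incident diagnosis necessarily co-occurs with
   its own code, and same-day repeat codes are ubiquitous in EHR data.
   When the lookback reaches before the start of available history the
   case is **excluded** with reason `insufficient observation history`
   rather than assumed clean: with less than a year of observation we
   cannot distinguish incident from prevalent disease. (With the default
   configuration this arises only for conditions whose recorded onset
   predates their in-study encounter, e.g. carried-over diagnoses;
   `phenotype_config()` refuses study periods that would make in-study
   onsets unevaluable.)
6. **Vaccine exposure.** A `exposure_vaccine` immunization with offset
   `Δ = index − administration` in the closed risk window `[0, 42]` days.
   Day 0 (same-day) qualifies. When several doses qualify, the smallest
   non-negative offset — the most recent dose at or before the diagnosis —
   is recorded; this is the deterministic rule needed for patients with
   multiple immunizations, and it attributes the event to the nearest
   plausible exposure.
7. **One case per patient.** The earliest qualifying index per patient,
   since validation counts patient-level cases.

Stages 3–6 are conjunctive predicates on a case, so permuting them changes
the attrition table but never the final candidate set; the tests exploit
this by checking the whole pipeline against an independent brute-force
evaluation of every (patient, condition, immunization) triple.

### Value sets

Code matching is exact, case-sensitive `(system, code)` equality after
trimming, with an optional per-entry `prefix` flag for ICD-10 families
(`I40` matches `I40.0`, `I40.9`, …). The shipped defaults (ICD-10-CM
I40.*/I41/I51.4/I30.*/I31.9/I32; LOINC troponin and CK-MB assays; CVX
207/208/211/212/213) are documented stand-ins meant to be replaced by a
site's curated lists via `load_valuesets()`. Only ICD-10-CM is used by
default; sites coding in SNOMED can add those entries to the same sets —
the matcher is code-system-agnostic.

## Retrieval and the multi-match exclusion

Exchange retrieval is simulated against the local registry. The matching
key is the minimal plausible demographic set — normalized full name
(case-folded, punctuation stripped, whitespace collapsed), birth date, and
sex — matched exactly. A case matching zero or multiple registry patients
is not retrieved; the multi-match rule mirrors the privacy practice of
refusing transfer when identity is ambiguous, and it is symmetric: if A's
demographics match B's, neither is retrievable.

Payload assembly applies per-resource-type windows: Observation,
DiagnosticReport and DocumentReference are clipped to the study period;
Condition, Encounter, Immunization, MedicationRequest, Procedure and
AllergyIntolerance carry full clinical history (the clean window needs
pre-study conditions); Location, Practitioner and Medication appear only
when referenced by an included record.

## Adjudication

Each retrieved case gets two independent reviews on the conventional
diagnostic-certainty scale (definite, probable, possible, doubtful), with
*insufficient evidence* as a separate fifth label for cases whose
documentation cannot support a determination. We deliberately separate
`possible` (adjudicated, counted as a false positive) from
`insufficient_evidence` (excluded from the primary PPV denominator):
the two concepts are often conflated in prose, but they enter the
statistics differently. Disagreements are settled by a third reviewer
consulted exactly once, whose label is final; the simulated tie-breaker
draws independently of the first two reviews, since nothing requires the
third reviewer to see them.

The reviewer simulator labels evidence-withheld cases
`insufficient_evidence` from both reviewers; otherwise reviewer 1 calls
the case positive with probability `sensitivity_to_truth` (0.9 by
default) when the latent label is true, choosing uniformly between
definite and probable (no information distinguishes them, and only their
union enters PPV), and reviewer 2 copies reviewer 1 with probability
`agreement_rate` (0.8) or redraws independently. Fixtures can pin
per-case classifications through the truth table's `fixed_class` column,
which is what makes the shipped deterministic scenario exactly
reproducible.

## Validation statistics

With final counts (definite, probable, possible, doubtful, insufficient):

- `TP = definite + probable`, `FP = possible + doubtful`;
- primary `PPV = TP / (TP + FP)`; alternate
  `PPV = TP / (TP + FP + insufficient)`, treating unverifiable cases as
  false positives (a conservative sensitivity analysis — it can never
  exceed the primary PPV);
- Agresti–Coull interval: `ñ = n + z²`, `p̃ = (x + z²/2)/ñ`, bounds
  `p̃ ± z√(p̃(1−p̃)/ñ)` clamped to [0, 1] (the raw formula can leave the
  unit interval at extreme counts; a proportion estimate must be a
  proportion). We use the exact normal quantile (z = 1.959964 at 95%);
  published intervals computed with rounded quantiles or adjacent
  adjusted-Wald variants can differ from ours by a percentage point or
  two at small n, which is why the tests pin our formula's own values
  (14/24 → 38.8–75.6%) rather than any externally printed interval.
- Cohen κ between the two primary reviewers, pre-tie-break, over all
  reviewed cases with `insufficient_evidence` as a fifth category (the
  reliability of the raters includes their ability to agree that evidence
  is missing). κ is undefined — and raises an error rather than silently
  returning 0 — when chance agreement is 1.
- Pooled two-sample proportion z test (no continuity correction) for
  comparing PPVs between sites.

Report percentages are rounded to one decimal for display only; stored
values keep full precision.

## The synthetic cohort

`generate_cohort()` emulates a hospital EHR over the study period with a
one-year lookback. Demographic category proportions default to the
marginals of a large academic health system's patient population (about
46% male, 61% White, 14% Hispanic, a quarter over 65). Design choices a
user should know:

- Planted categories carry exactly the structure their name implies, with
  vaccination-to-diagnosis offsets drawn uniformly on the stated integer
  ranges (`{0..42}` in-window, `{43..120}` out-of-window, prior diagnoses
  at `index − {30..364}` days). Uniform offsets maximize boundary
  coverage; no empirical latency distribution is assumed.
- Duplicate-demographic cases clone (name key, birth date, sex) onto a
  distinct background patient, which is precisely the condition the
  multi-match exclusion tests.
- Insufficient-evidence cases keep the detection-relevant supporting
  observation (so they are still flagged) but their latent
  `evidence_complete` flag is false and their diagnostic-report
  documentation is withheld — flagged but unconfirmable, the same
  asymmetry seen in practice with missing lab results.
- Planted cases are drawn from adult age strata so that every historical
  record postdates birth; background patients get 1–3 encounters
  (15/75/10% inpatient/outpatient/emergency), non-target diagnoses, and
  COVID-19 vaccination with probability 0.6 if aged 5+. Defaults
  `truth_ppv = 0.583` and `insufficient_evidence_rate = 0.077` mirror the
  rates a validation study of this phenotype would plausibly observe.
- Names come from a small seeded pool; only the normalized `name_key` is
  consumed downstream. Identical spec + seed reproduces the NDJSON byte
  for byte.

What the generator does **not** emulate: clinical-note text (document
references are stubs), realistic myocarditis incidence rates, coding
errors and transfers between systems, or correlated comorbidity
structure. Passing tests therefore demonstrate the correctness of the
*rules* — window arithmetic, set matching, attrition accounting,
statistics — not the clinical performance of any code list on real data,
where PPV is driven by documentation quality and alternative diagnoses
the simulator does not model.

`consort_scenario()` is a fixed cohort (120 patients, seed 20201214)
whose pipeline run produces a known chain — 30 flagged, 4 multi-match
exclusions, 26 retrieved, 2 insufficient, 24 adjudicated as 3/11/0/10 —
used as the end-to-end regression fixture.

## Problem sizes and numerical checks

The test suite exercises: round-trip and reject accounting on
100-patient bundles; oracle equivalence of `detect()` against a
brute-force implementation on 1,000-patient cohorts spanning all planted
categories; demographic-marginal convergence at 10,000 patients (±2
percentage points); reviewer-agreement convergence at 10,000 simulated
cases; and Agresti–Coull empirical coverage over 10,000 binomial
replicates per (p, n) cell at p ∈ {0.2, 0.5, 0.8}, n ∈ {20, 50},
required to lie in [93%, 97%]. These sizes keep the full suite under a
minute while leaving Monte-Carlo error well below the asserted
tolerances.

## Known limitations

- The phenotype is deliberately simple; no NLP over notes, no
  terminology-server expansion or cross-system code mapping.
- Retrieval is simulated locally; no network transport or FHIR search
  API is implemented.
- The observed-only design estimates PPV but not sensitivity,
  specificity or NPV: cases the algorithm misses are never reviewed.
- Whether a multi-code, multi-encounter patient's index event should be
  the earliest code or the earliest encounter is a genuine modeling
  choice; we use the earliest qualifying condition onset, configurable
  indirectly through the value sets and care settings.
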