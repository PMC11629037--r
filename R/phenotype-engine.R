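#' @title Phenotype detection engine
#' @description The rules-based computable phenotype: an ordered sequence of
#'   filter stages taking raw encounters to flagged case candidates, with
#'   CONSORT-style attrition accounting at every stage.
#'
#'   Stage order: (1) encounters within the study period; (2) care-setting
#'   filter (inpatient by default); (3) target-diagnosis condition match on a
#'   qualifying encounter, ignoring admitting diagnoses; (4) supporting
#'   evidence within a window around the index diagnosis; (5) clean window —
#'   no qualifying diagnosis in the lookback, and enough observed history to
#'   evaluate it; (6) vaccine exposure within the postvaccination risk
#'   window; (7) collapse to one case per patient (earliest index).
#' @name phenotype_engine
NULL

#' Phenotype configuration
#'
#' @param study_start,study_end study period bounds (defaults: 2020-12-14,
#'   the start of COVID-19 vaccine emergency use authorization, through
#'   2023-04-28).
#' @param observation_start start of available history; must precede
#'   `study_start` by at least `clean_window_days` so that every in-study
#'   index date has an evaluable clean window (default 2019-12-14).
#' @param risk_window_days closed integer interval of qualifying
#'   diagnosis-minus-vaccination offsets in days; default `c(0, 42)`,
#'   day 0 (same-day) included.
#' @param clean_window_days lookback (days) that must be free of the target
#'   diagnosis for the case to count as incident; default 365.
#' @param care_settings encounter settings eligible to anchor a case;
#'   default `"inpatient"`.
#' @param require_supporting_evidence require at least one
#'   supporting-evidence observation near the index date (default TRUE).
#' @param supporting_evidence_window_days half-width (days) of the symmetric
#'   window around the index date searched for supporting evidence;
#'   default 7.
#' @param exclude_admitting_only ignore conditions recorded with an
#'   admitting diagnosis role when selecting the index event (default TRUE).
#' @param one_case_per_patient keep only the earliest qualifying index date
#'   per patient (default TRUE).
#' @return A `phenotype_config` list.
#' @export
phenotype_config <- function(study_start = as.Date("2020-12-14"),
                             study_end = as.Date("2023-04-28"),
                             observation_start = as.Date("2019-12-14"),
                             risk_window_days = c(0L, 42L),
                             clean_window_days = 365L,
                             care_settings = "inpatient",
                             require_supporting_evidence = TRUE,
                             supporting_evidence_window_days = 7L,
                             exclude_admitting_only = TRUE,
                             one_case_per_patient = TRUE) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  observation_start <- as.Date(observation_start)
  stopifnot(length(risk_window_days) == 2, risk_window_days[1] >= 0,
            risk_window_days[1] <= risk_window_days[2],
            clean_window_days >= 1, study_end >= study_start,
            all(care_settings %in% CARE_SETTINGS))
  if (study_start < observation_start + clean_window_days) {
    abort("study_start must be at least clean_window_days after observation_start")
  }
  structure(list(study_start = study_start, study_end = study_end,
                 observation_start = observation_start,
                 risk_window_days = as.integer(risk_window_days),
                 clean_window_days = as.integer(clean_window_days),
                 care_settings = care_settings,
                 require_supporting_evidence = require_supporting_evidence,
                 supporting_evidence_window_days =
                   as.integer(supporting_evidence_window_days),
                 exclude_admitting_only = exclude_admitting_only,
                 one_case_per_patient = one_case_per_patient),
            class = "phenotype_config")
}

#' Offset of a diagnosis inside the postvaccination risk window
#'
#' @param vaccination_date,diagnosis_date `Date` vectors (recycled).
#' @param window closed integer interval `c(lower, upper)` in days;
#'   default `c(0, 42)`.
#' @return Integer vector of whole-day offsets
#'   (`diagnosis_date - vaccination_date`) where the offset falls inside the
#'   window, `NA` elsewhere. Same-day vaccination and diagnosis is offset 0
#'   and qualifies under the default window.
#' @export
in_risk_window <- function(vaccination_date, diagnosis_date,
                           window = c(0L, 42L)) {
  offset <- as.integer(as.Date(diagnosis_date) - as.Date(vaccination_date))
  ifelse(offset >= window[1] & offset <= window[2], offset, NA_integer_)
}

#' Select the qualifying vaccine exposure for a diagnosis date
#'
#' Among immunizations whose vaccine code is in the exposure value set and
#' whose offset to the diagnosis lies in the risk window, returns the dose
#' with the smallest offset — i.e. the most recent dose at or before the
#' diagnosis. Ties (same administration date) break on immunization id.
#'
#' @param immunizations immunization tibble (may be empty or span patients;
#'   filter to one patient for per-case use).
#' @param diagnosis_date index diagnosis `Date`.
#' @param vaccine_valueset exposure-role value-set tibble.
#' @param window risk window `c(lower, upper)` in days.
#' @return A one-row tibble `(immunization_id, administration_date,
#'   exposure_offset_days)`, or NULL when no dose qualifies.
#' @export
select_exposure <- function(immunizations, diagnosis_date, vaccine_valueset,
                            window = c(0L, 42L)) {
  if (!nrow(immunizations)) return(NULL)
  imm <- immunizations[coding_in_valueset(immunizations$system,
                                          immunizations$code,
                                          vaccine_valueset), ]
  if (!nrow(imm)) return(NULL)
  imm$exposure_offset_days <- in_risk_window(imm$administration_date,
                                             diagnosis_date, window)
  imm <- imm[!is.na(imm$exposure_offset_days), ]
  if (!nrow(imm)) return(NULL)
  imm <- imm[order(imm$exposure_offset_days, imm$immunization_id), ]
  imm[1, c("immunization_id", "administration_date", "exposure_offset_days")]
}

#' Clean-window check: is the diagnosis incident?
#'
#' TRUE iff the patient has no target-valueset condition with onset in the
#' half-open interval `[index_date - lookback_days, index_date)`. The index
#' day itself is not disqualifying: an incident diagnosis necessarily
#' co-occurs with its own code.
#'
#' @param conditions condition tibble (any patients).
#' @param patient_id patient to check.
#' @param index_date index diagnosis `Date`.
#' @param target_valueset target-diagnosis value-set tibble.
#' @param lookback_days clean-window length in days (default 365).
#' @return Logical scalar.
#' @export
passes_clean_window <- function(conditions, patient_id, index_date,
                                target_valueset, lookback_days = 365L) {
  cc <- conditions[conditions$patient_id == patient_id, ]
  if (!nrow(cc)) return(TRUE)
  cc <- cc[coding_in_valueset(cc$system, cc$code, target_valueset), ]
  if (!nrow(cc)) return(TRUE)
  !any(cc$onset_date >= index_date - lookback_days &
         cc$onset_date < index_date)
}

DETECT_STAGES <- c("study_period", "care_setting", "target_diagnosis",
                   "supporting_evidence", "clean_window", "vaccine_exposure",
                   "one_case_per_patient")

#' Run the phenotype detection algorithm over a bundle
#'
#' Applies the seven filter stages in order and reports attrition at each
#' one. The unit of counting switches from encounters (stages 1-2) to
#' candidate case events — a (patient, encounter, condition) triple —
#' (stages 3-6) and finally to patients.
#'
#' @param bundle an `ehr_bundle`.
#' @param valuesets value-set tibble providing all three roles.
#' @param config a [phenotype_config()].
#' @return A list with:
#'   \describe{
#'     \item{candidates}{tibble of flagged cases: `patient_id`,
#'       `index_diagnosis_date`, `index_encounter_id`, `index_condition_id`,
#'       matched code, `qualifying_immunization_id`, `exposure_offset_days`,
#'       `supporting_evidence_ids` (`;`-joined), and the demographics
#'       snapshot used for retrieval matching.}
#'     \item{attrition}{tibble `(stage, unit, entering, surviving)`.}
#'     \item{exclusions}{tibble of excluded case events with the stage and
#'       reason (e.g. `insufficient observation history` for cases whose
#'       clean window predates the observation period).}
#'   }
#' @export
detect <- function(bundle, valuesets, config = phenotype_config()) {
  validate_bundle(bundle)
  vs_target <- valueset_for_role(valuesets, "target_diagnosis")
  vs_evid <- valueset_for_role(valuesets, "supporting_evidence",
                               required = config$require_supporting_evidence)
  vs_vax <- valueset_for_role(valuesets, "exposure_vaccine")

  attr_rows <- list()
  excl_rows <- list()
  note_stage <- function(stage, unit, entering, surviving) {
    attr_rows[[length(attr_rows) + 1L]] <<-
      tibble(stage = stage, unit = unit, entering = entering,
             surviving = surviving)
  }
  note_excl <- function(cases, stage, reason) {
    if (!nrow(cases)) return(invisible())
    excl_rows[[length(excl_rows) + 1L]] <<-
      tibble(patient_id = cases$patient_id,
             condition_id = cases$condition_id,
             index_diagnosis_date = cases$onset_date,
             stage = stage, reason = reason)
  }

  # stage 1: encounters in the study period (anchored on admission date)
  enc0 <- bundle$encounters
  enc1 <- filter(enc0, .data$start_date >= config$study_start,
                 .data$start_date <= config$study_end)
  note_stage("study_period", "encounters", nrow(enc0), nrow(enc1))

  # stage 2: care setting
  enc2 <- filter(enc1, .data$care_setting %in% config$care_settings)
  note_stage("care_setting", "encounters", nrow(enc1), nrow(enc2))

  # stage 3: target diagnosis on a qualifying encounter
  cases <- bundle$conditions %>%
    filter(!is.na(.data$encounter_id)) %>%
    inner_join(select(enc2, "encounter_id", "care_setting"),
               by = "encounter_id")
  entering3 <- nrow(cases)
  keep <- coding_in_valueset(cases$system, cases$code, vs_target)
  if (config$exclude_admitting_only) {
    keep <- keep & cases$diagnosis_role != "admitting"
  }
  cases3 <- cases[keep, ]
  note_stage("target_diagnosis", "cases", entering3, nrow(cases3))

  # stage 4: supporting evidence near the index date
  if (config$require_supporting_evidence) {
    evid <- bundle$observations[coding_in_valueset(bundle$observations$system,
                                                   bundle$observations$code,
                                                   vs_evid), ]
    w <- config$supporting_evidence_window_days
    ev_ids <- vapply(seq_len(nrow(cases3)), function(i) {
      e <- evid[evid$patient_id == cases3$patient_id[[i]] &
                  abs(as.integer(evid$effective_date -
                                   cases3$onset_date[[i]])) <= w, ]
      paste(sort(e$observation_id), collapse = ";")
    }, character(1))
    cases3$supporting_evidence_ids <- ev_ids
    cases4 <- cases3[nzchar(ev_ids), ]
    note_excl(cases3[!nzchar(ev_ids), ], "supporting_evidence",
              "no supporting evidence in window")
  } else {
    cases3$supporting_evidence_ids <- ""
    cases4 <- cases3
  }
  note_stage("supporting_evidence", "cases", nrow(cases3), nrow(cases4))

  # stage 5: clean window (requires evaluable history)
  if (nrow(cases4)) {
    lb <- config$clean_window_days
    evaluable <- cases4$onset_date - lb >= config$observation_start
    clean <- vapply(seq_len(nrow(cases4)), function(i) {
      evaluable[[i]] && passes_clean_window(bundle$conditions,
                                            cases4$patient_id[[i]],
                                            cases4$onset_date[[i]],
                                            vs_target, lb)
    }, logical(1))
    note_excl(cases4[!evaluable, ], "clean_window",
              "insufficient observation history")
    note_excl(cases4[evaluable & !clean, ], "clean_window",
              "prior qualifying diagnosis in clean window")
    cases5 <- cases4[clean, ]
  } else {
    cases5 <- cases4
  }
  note_stage("clean_window", "cases", nrow(cases4), nrow(cases5))

  # stage 6: vaccine exposure in the risk window
  if (nrow(cases5)) {
    expo <- lapply(seq_len(nrow(cases5)), function(i) {
      select_exposure(bundle$immunizations[bundle$immunizations$patient_id ==
                                             cases5$patient_id[[i]], ],
                      cases5$onset_date[[i]], vs_vax,
                      config$risk_window_days)
    })
    has_expo <- !vapply(expo, is.null, logical(1))
    note_excl(cases5[!has_expo, ], "vaccine_exposure",
              "no qualifying vaccine exposure in risk window")
    cases6 <- cases5[has_expo, ]
    if (nrow(cases6)) {
      ed <- bind_rows(expo[has_expo])
      cases6$qualifying_immunization_id <- ed$immunization_id
      cases6$exposure_offset_days <- ed$exposure_offset_days
    } else {
      cases6$qualifying_immunization_id <- character()
      cases6$exposure_offset_days <- integer()
    }
  } else {
    cases6 <- mutate(cases5, qualifying_immunization_id = character(0),
                     exposure_offset_days = integer(0))
  }
  note_stage("vaccine_exposure", "cases", nrow(cases5), nrow(cases6))

  # stage 7: one case per patient (earliest index; deterministic tie-break)
  if (config$one_case_per_patient && nrow(cases6)) {
    cases7 <- cases6 %>%
      arrange(.data$patient_id, .data$onset_date, .data$condition_id) %>%
      group_by(.data$patient_id) %>% slice(1) %>% ungroup()
  } else {
    cases7 <- cases6
  }
  note_stage("one_case_per_patient", "patients", nrow(cases6),
             length(unique(cases7$patient_id)))

  demo <- select(bundle$patients, "patient_id", "name_key", "birth_date",
                 "sex")
  candidates <- cases7 %>%
    rename(index_diagnosis_date = "onset_date",
           index_encounter_id = "encounter_id",
           index_condition_id = "condition_id",
           matched_system = "system", matched_code = "code") %>%
    left_join(demo, by = "patient_id") %>%
    select("patient_id", "index_diagnosis_date", "index_encounter_id",
           "index_condition_id", "matched_system", "matched_code",
           "qualifying_immunization_id", "exposure_offset_days",
           "supporting_evidence_ids", "name_key", "birth_date", "sex") %>%
    arrange(.data$patient_id)

  attrition <- bind_rows(attr_rows)
  stopifnot(all(attrition$surviving <= attrition$entering))
  exclusions <- if (length(excl_rows)) bind_rows(excl_rows) else
    tibble(patient_id = character(), condition_id = character(),
           index_diagnosis_date = as.Date(character()), stage = character(),
           reason = character())
  list(candidates = candidates, attrition = attrition,
       exclusions = exclusions)
}
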