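# Independent brute-force implementations used as oracles. Deliberately
# written as plain loops over single records, sharing no code with the
# package's vectorized/data-frame implementation.

oracle_member <- function(system, code, vs) {
  system <- trimws(system); code <- trimws(code)
  for (j in seq_len(nrow(vs))) {
    if (system == vs$system[[j]]) {
      if (vs$prefix[[j]]) {
        if (startsWith(code, vs$code[[j]])) return(TRUE)
      } else if (code == vs$code[[j]]) {
        return(TRUE)
      }
    }
  }
  FALSE
}

empty_oracle_candidates <- function() {
  tibble::tibble(patient_id = character(),
                 index_diagnosis_date = as.Date(character()),
                 index_condition_id = character(),
                 qualifying_immunization_id = character(),
                 exposure_offset_days = integer())
}

# Tests every (patient, condition, immunization) triple directly against the
# stage predicates; keeps the earliest qualifying index per patient.
oracle_detect <- function(bundle, valuesets, config) {
  tgt <- valuesets[valuesets$role == "target_diagnosis", ]
  evd <- valuesets[valuesets$role == "supporting_evidence", ]
  vax <- valuesets[valuesets$role == "exposure_vaccine", ]
  out <- list()
  for (pid in bundle$patients$patient_id) {
    conds <- bundle$conditions[bundle$conditions$patient_id == pid, ]
    obs <- bundle$observations[bundle$observations$patient_id == pid, ]
    imms <- bundle$immunizations[bundle$immunizations$patient_id == pid, ]
    best <- NULL
    for (ci in seq_len(nrow(conds))) {
      cond <- conds[ci, ]
      if (is.na(cond$encounter_id)) next
      enc <- bundle$encounters[bundle$encounters$encounter_id ==
                                 cond$encounter_id, ]
      if (!nrow(enc)) next
      if (enc$start_date < config$study_start ||
          enc$start_date > config$study_end) next
      if (!enc$care_setting %in% config$care_settings) next
      if (!oracle_member(cond$system, cond$code, tgt)) next
      if (config$exclude_admitting_only &&
          cond$diagnosis_role == "admitting") next
      if (config$require_supporting_evidence) {
        ok <- FALSE
        for (oi in seq_len(nrow(obs))) {
          if (oracle_member(obs$system[[oi]], obs$code[[oi]], evd) &&
              abs(as.integer(obs$effective_date[[oi]] - cond$onset_date)) <=
                config$supporting_evidence_window_days) ok <- TRUE
        }
        if (!ok) next
      }
      if (cond$onset_date - config$clean_window_days <
            config$observation_start) next
      dirty <- FALSE
      for (cj in seq_len(nrow(conds))) {
        if (oracle_member(conds$system[[cj]], conds$code[[cj]], tgt) &&
            conds$onset_date[[cj]] >=
              cond$onset_date - config$clean_window_days &&
            conds$onset_date[[cj]] < cond$onset_date) dirty <- TRUE
      }
      if (dirty) next
      chosen <- NULL
      for (ii in seq_len(nrow(imms))) {
        if (!oracle_member(imms$system[[ii]], imms$code[[ii]], vax)) next
        off <- as.integer(cond$onset_date -
                            imms$administration_date[[ii]])
        if (off < config$risk_window_days[[1]] ||
            off > config$risk_window_days[[2]]) next
        if (is.null(chosen) || off < chosen$off ||
            (off == chosen$off &&
               imms$immunization_id[[ii]] < chosen$id)) {
          chosen <- list(off = off, id = imms$immunization_id[[ii]])
        }
      }
      if (is.null(chosen)) next
      cand <- list(patient_id = pid, index_diagnosis_date = cond$onset_date,
                   index_condition_id = cond$condition_id,
                   qualifying_immunization_id = chosen$id,
                   exposure_offset_days = chosen$off)
      if (is.null(best) ||
          cand$index_diagnosis_date < best$index_diagnosis_date ||
          (cand$index_diagnosis_date == best$index_diagnosis_date &&
             cand$index_condition_id < best$index_condition_id)) {
        best <- cand
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  if (!length(out)) return(empty_oracle_candidates())
  dplyr::arrange(dplyr::bind_rows(lapply(out, tibble::as_tibble)),
                 patient_id)
}

# Brute-force structural check of one patient's planted category against the
# generated records; returns TRUE when the records carry the structure the
# category name promises.
oracle_category_ok <- function(bundle, pid, category, valuesets) {
  tgt <- valuesets[valuesets$role == "target_diagnosis", ]
  evd <- valuesets[valuesets$role == "supporting_evidence", ]
  vax <- valuesets[valuesets$role == "exposure_vaccine", ]
  scan <- function(tab, vs) {
    keep <- vapply(seq_len(nrow(tab)), function(i) {
      oracle_member(tab$system[[i]], tab$code[[i]], vs)
    }, logical(1))
    tab[keep, ]
  }
  tcond <- scan(bundle$conditions[bundle$conditions$patient_id == pid, ],
                tgt)
  vimms <- scan(bundle$immunizations[bundle$immunizations$patient_id ==
                                       pid, ], vax)
  eobs <- scan(bundle$observations[bundle$observations$patient_id == pid, ],
               evd)
  enc_of <- function(eid) {
    bundle$encounters[bundle$encounters$encounter_id == eid, ]
  }
  index_rows <- tcond[!is.na(tcond$encounter_id) &
                        tcond$diagnosis_role == "final", ]
  if (category == "background") return(nrow(tcond) == 0)
  if (!nrow(index_rows)) return(FALSE)
  d <- min(index_rows$onset_date)
  setting <- enc_of(index_rows$encounter_id[[which.min(index_rows$onset_date)]])$care_setting
  offsets <- as.integer(d - vimms$administration_date)
  min_off <- if (length(offsets[offsets >= 0])) min(offsets[offsets >= 0])
  else NA_integer_
  has_evidence <- nrow(eobs) > 0 &&
    any(abs(as.integer(eobs$effective_date - d)) <= 7)
  prior <- any(tcond$onset_date >= d - 365 & tcond$onset_date < d)
  switch(category,
    true_in_window = ,
    duplicate_demographics =
      setting == "inpatient" && !is.na(min_off) && min_off <= 42 &&
        has_evidence && !prior,
    out_of_window =
      setting == "inpatient" && (is.na(min_off) || min_off > 42) &&
        length(offsets) > 0 && any(offsets >= 43 & offsets <= 120),
    prevalent = setting == "inpatient" && prior,
    outpatient_only = setting != "inpatient",
    unvaccinated = setting == "inpatient" && nrow(vimms) == 0,
    FALSE)
}
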