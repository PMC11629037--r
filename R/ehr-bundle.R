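#' @title EHR bundle container
#' @description An `ehr_bundle` is a patient-linked collection of typed
#'   clinical records (patients, encounters, conditions, immunizations,
#'   observations) plus opaque pass-through FHIR resources kept as raw NDJSON
#'   lines. All dates are held at day granularity (`Date`); timestamps are
#'   truncated on ingest because every temporal rule in the phenotype is
#'   expressed in whole days.
#' @name ehr_bundle
NULL

#' Resource types interpreted into typed columns
#' @keywords internal
TYPED_RESOURCES <- c("Patient", "Encounter", "Condition", "Immunization",
                     "Observation")

#' Resource types carried verbatim (byte-for-byte on round-trip)
#' @keywords internal
PASSTHROUGH_RESOURCES <- c("AllergyIntolerance", "DiagnosticReport",
                           "DocumentReference", "MedicationRequest",
                           "Procedure", "Location", "Practitioner",
                           "Medication")

SEX_LEVELS       <- c("male", "female", "other")
RACE_LEVELS      <- c("white", "black", "asian_pacific_islander",
                      "american_indian_alaska_native", "other", "unknown",
                      "declined")
ETHNICITY_LEVELS <- c("hispanic", "non_hispanic", "unknown")
CARE_SETTINGS    <- c("inpatient", "outpatient", "emergency", "other")
DIAGNOSIS_ROLES  <- c("admitting", "final", "other")

empty_patients <- function() {
  tibble(patient_id = character(), name = character(),
         name_key = character(), birth_date = as.Date(character()),
         sex = character(), race = character(), ethnicity = character())
}
empty_encounters <- function() {
  tibble(encounter_id = character(), patient_id = character(),
         care_setting = character(), start_date = as.Date(character()),
         end_date = as.Date(character()))
}
empty_conditions <- function() {
  tibble(condition_id = character(), patient_id = character(),
         encounter_id = character(), system = character(), code = character(),
         onset_date = as.Date(character()), diagnosis_role = character())
}
empty_immunizations <- function() {
  tibble(immunization_id = character(), patient_id = character(),
         system = character(), code = character(),
         administration_date = as.Date(character()))
}
empty_observations <- function() {
  tibble(observation_id = character(), patient_id = character(),
         system = character(), code = character(),
         effective_date = as.Date(character()), value = numeric())
}
empty_rejects <- function() {
  tibble(file = character(), line = integer(), reason = character())
}

#' Construct an EHR bundle
#'
#' @param patients,encounters,conditions,immunizations,observations tibbles
#'   with the typed-record columns (see [ehr_bundle]); missing arguments
#'   default to empty tables.
#' @param passthrough named list of character vectors, one element per
#'   pass-through FHIR resource type, each vector holding raw NDJSON lines.
#' @param rejects tibble of rejected input lines (`file`, `line`, `reason`).
#' @param validate check referential integrity and invariants (default TRUE).
#' @return An object of class `ehr_bundle`.
#' @export
new_bundle <- function(patients = empty_patients(),
                       encounters = empty_encounters(),
                       conditions = empty_conditions(),
                       immunizations = empty_immunizations(),
                       observations = empty_observations(),
                       passthrough = list(),
                       rejects = empty_rejects(),
                       validate = TRUE) {
  b <- structure(
    list(patients = as_tibble(patients), encounters = as_tibble(encounters),
         conditions = as_tibble(conditions),
         immunizations = as_tibble(immunizations),
         observations = as_tibble(observations),
         passthrough = passthrough, rejects = as_tibble(rejects)),
    class = "ehr_bundle")
  if (validate) validate_bundle(b)
  b
}

#' Validate an EHR bundle's invariants
#'
#' Checks patient-id uniqueness, referential integrity of every clinical
#' record, closed enums, and encounter date ordering. Called by
#' [new_bundle()]; errors on the first violation.
#'
#' @param b an `ehr_bundle`.
#' @return `b`, invisibly.
#' @export
validate_bundle <- function(b) {
  stopifnot(inherits(b, "ehr_bundle"))
  if (anyDuplicated(b$patients$patient_id)) {
    abort("duplicate patient_id in bundle")
  }
  pids <- b$patients$patient_id
  for (tab in c("encounters", "conditions", "immunizations", "observations")) {
    orphan <- setdiff(b[[tab]]$patient_id, pids)
    if (length(orphan)) {
      abort(sprintf("%s reference unknown patient_id: %s", tab,
                    paste(head(orphan, 3), collapse = ", ")))
    }
  }
  if (nrow(b$encounters) &&
      any(b$encounters$end_date < b$encounters$start_date)) {
    abort("encounter end_date precedes start_date")
  }
  chk_enum <- function(x, levels, what) {
    bad <- setdiff(unique(x[!is.na(x)]), levels)
    if (length(bad)) abort(sprintf("invalid %s: %s", what, bad[[1]]))
  }
  chk_enum(b$patients$sex, SEX_LEVELS, "sex")
  chk_enum(b$patients$race, RACE_LEVELS, "race")
  chk_enum(b$patients$ethnicity, ETHNICITY_LEVELS, "ethnicity")
  chk_enum(b$encounters$care_setting, CARE_SETTINGS, "care_setting")
  chk_enum(b$conditions$diagnosis_role, DIAGNOSIS_ROLES, "diagnosis_role")
  invisible(b)
}

#' @export
print.ehr_bundle <- function(x, ...) {
  cat("<ehr_bundle>\n")
  cat(sprintf("  patients:      %d\n", nrow(x$patients)))
  cat(sprintf("  encounters:    %d\n", nrow(x$encounters)))
  cat(sprintf("  conditions:    %d\n", nrow(x$conditions)))
  cat(sprintf("  immunizations: %d\n", nrow(x$immunizations)))
  cat(sprintf("  observations:  %d\n", nrow(x$observations)))
  if (length(x$passthrough)) {
    cat(sprintf("  pass-through:  %s\n",
                paste(sprintf("%s (%d)", names(x$passthrough),
                              lengths(x$passthrough)), collapse = ", ")))
  }
  if (nrow(x$rejects)) cat(sprintf("  rejects:       %d\n", nrow(x$rejects)))
  invisible(x)
}

#' Normalize a person name for demographic matching
#'
#' Case-folds, strips punctuation, and collapses runs of whitespace. The
#' result (`name_key`) is the only name-derived field consumed by the
#' matching logic.
#'
#' @param x character vector of full names.
#' @return character vector of normalized keys.
#' @export
normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}
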