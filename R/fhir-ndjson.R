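#' @title FHIR R4 NDJSON input/output
#' @description Readers and writers for bulk-export-style FHIR R4 NDJSON,
#'   one file per resource type, named `<ResourceType>.ndjson`. Only the
#'   fields used by the phenotype are interpreted; resource types outside the
#'   typed set are carried verbatim. Lines that fail parsing or schema
#'   validation are collected in a rejects table with a reason, never dropped
#'   silently.
#' @name fhir_ndjson
NULL

FHIR_CLASS_BY_SETTING <- c(inpatient = "IMP", outpatient = "AMB",
                           emergency = "EMER", other = "OTH")
FHIR_SETTING_BY_CLASS <- setNames(names(FHIR_CLASS_BY_SETTING),
                                  FHIR_CLASS_BY_SETTING)
US_CORE_RACE <- "http://hl7.org/fhir/us/core/StructureDefinition/us-core-race"
US_CORE_ETHNICITY <-
  "http://hl7.org/fhir/us/core/StructureDefinition/us-core-ethnicity"
ACT_CODE_SYSTEM <- "http://terminology.hl7.org/CodeSystem/v3-ActCode"

fhir_date <- function(x) {
  if (is.null(x) || !nzchar(x)) return(as.Date(NA))
  as.Date(substr(x, 1, 10), format = "%Y-%m-%d", optional = TRUE)
}

ref_id <- function(ref, type) {
  if (is.null(ref)) return(NA_character_)
  sub(paste0("^", type, "/"), "", ref)
}

first_coding <- function(codeable) {
  cd <- codeable$coding[[1]]
  if (is.null(cd$system) || is.null(cd$code) ||
      !nzchar(trimws(cd$code %||% ""))) {
    abort("missing or empty coding")
  }
  list(system = trimws(cd$system), code = trimws(cd$code))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- per-resource parsers: return a one-row list of typed fields, or stop() --

parse_patient_line <- function(obj) {
  if (is.null(obj$id)) abort("missing id")
  bd <- fhir_date(obj$birthDate)
  if (is.na(bd)) abort("missing or invalid birthDate")
  nm <- obj$name[[1]]$text
  if (is.null(nm) || !nzchar(nm)) abort("missing name")
  sex <- obj$gender %||% "other"
  if (!sex %in% SEX_LEVELS) sex <- "other"
  race <- "unknown"; eth <- "unknown"
  for (ext in obj$extension %||% list()) {
    if (identical(ext$url, US_CORE_RACE)) race <- ext$valueString %||% "unknown"
    if (identical(ext$url, US_CORE_ETHNICITY)) eth <- ext$valueString %||% "unknown"
  }
  if (!race %in% RACE_LEVELS) abort(sprintf("invalid race: %s", race))
  if (!eth %in% ETHNICITY_LEVELS) abort(sprintf("invalid ethnicity: %s", eth))
  list(patient_id = obj$id, name = nm, name_key = normalize_name(nm),
       birth_date = bd, sex = sex, race = race, ethnicity = eth)
}

parse_encounter_line <- function(obj) {
  if (is.null(obj$id)) abort("missing id")
  pid <- ref_id(obj$subject$reference, "Patient")
  if (is.na(pid)) abort("missing subject reference")
  setting <- FHIR_SETTING_BY_CLASS[obj$class$code %||% "OTH"]
  if (is.na(setting)) setting <- "other"
  start <- fhir_date(obj$period$start)
  if (is.na(start)) abort("missing or invalid period.start")
  end <- fhir_date(obj$period$end)
  if (is.na(end)) end <- start
  if (end < start) abort("period end precedes start")
  list(encounter_id = obj$id, patient_id = pid,
       care_setting = unname(setting), start_date = start, end_date = end)
}

parse_condition_line <- function(obj) {
  if (is.null(obj$id)) abort("missing id")
  pid <- ref_id(obj$subject$reference, "Patient")
  if (is.na(pid)) abort("missing subject reference")
  cd <- first_coding(obj$code)
  onset <- fhir_date(obj$onsetDateTime)
  if (is.na(onset)) abort("missing or invalid onsetDateTime")
  role <- obj$category[[1]]$coding[[1]]$code %||% "other"
  if (!role %in% DIAGNOSIS_ROLES) role <- "other"
  list(condition_id = obj$id, patient_id = pid,
       encounter_id = ref_id(obj$encounter$reference, "Encounter"),
       system = cd$system, code = cd$code, onset_date = onset,
       diagnosis_role = role)
}

parse_immunization_line <- function(obj) {
  if (is.null(obj$id)) abort("missing id")
  pid <- ref_id(obj$patient$reference, "Patient")
  if (is.na(pid)) abort("missing patient reference")
  cd <- first_coding(obj$vaccineCode)
  adm <- fhir_date(obj$occurrenceDateTime)
  if (is.na(adm)) abort("missing or invalid occurrenceDateTime")
  list(immunization_id = obj$id, patient_id = pid, system = cd$system,
       code = cd$code, administration_date = adm)
}

parse_observation_line <- function(obj) {
  if (is.null(obj$id)) abort("missing id")
  pid <- ref_id(obj$subject$reference, "Patient")
  if (is.na(pid)) abort("missing subject reference")
  cd <- first_coding(obj$code)
  eff <- fhir_date(obj$effectiveDateTime)
  if (is.na(eff)) abort("missing or invalid effectiveDateTime")
  val <- obj$valueQuantity$value
  list(observation_id = obj$id, patient_id = pid, system = cd$system,
       code = cd$code, effective_date = eff,
       value = if (is.null(val)) NA_real_ else as.numeric(val))
}

TYPED_PARSERS <- list(Patient = parse_patient_line,
                      Encounter = parse_encounter_line,
                      Condition = parse_condition_line,
                      Immunization = parse_immunization_line,
                      Observation = parse_observation_line)

#' Read an EHR bundle from FHIR R4 NDJSON files
#'
#' @param paths either a directory containing `<ResourceType>.ndjson` files,
#'   or a named character vector mapping resource-type names to file paths.
#'   A `Patient` file is mandatory.
#' @return An `ehr_bundle`. Lines that are malformed, carry the wrong
#'   `resourceType`, fail field validation, or reference an unknown patient
#'   are reported in `bundle$rejects` (columns `file`, `line`, `reason`);
#'   accepted plus rejected lines always account for every input line.
#' @export
read_bundle <- function(paths) {
  if (length(paths) == 1L && is.null(names(paths)) && dir.exists(paths)) {
    files <- list.files(paths, pattern = "\\.ndjson$", full.names = TRUE)
    paths <- setNames(files, sub("\\.ndjson$", "", basename(files)))
  }
  if (!"Patient" %in% names(paths)) {
    abort("no Patient resource file provided")
  }
  typed <- list(Patient = list(), Encounter = list(), Condition = list(),
                Immunization = list(), Observation = list())
  passthrough <- list()
  rejects <- list()
  for (rtype in names(paths)) {
    lines <- readLines(paths[[rtype]], warn = FALSE)
    lines <- lines[nzchar(lines)]
    keep_raw <- !rtype %in% TYPED_RESOURCES
    kept <- character()
    for (i in seq_along(lines)) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                      error = function(e) NULL)
      if (is.null(obj)) {
        rejects[[length(rejects) + 1L]] <-
          list(file = rtype, line = i, reason = "malformed JSON")
        next
      }
      if (!identical(obj$resourceType, rtype)) {
        rejects[[length(rejects) + 1L]] <-
          list(file = rtype, line = i,
               reason = sprintf("unexpected resourceType: %s",
                                obj$resourceType %||% "<none>"))
        next
      }
      if (keep_raw) {
        kept <- c(kept, lines[[i]])
      } else {
        rec <- tryCatch(TYPED_PARSERS[[rtype]](obj), error = function(e) {
          rejects[[length(rejects) + 1L]] <<-
            list(file = rtype, line = i, reason = conditionMessage(e))
          NULL
        })
        if (!is.null(rec)) typed[[rtype]][[length(typed[[rtype]]) + 1L]] <- rec
      }
    }
    if (keep_raw) passthrough[[rtype]] <- kept
  }
  to_tbl <- function(recs, empty) {
    if (!length(recs)) return(empty)
    bind_rows(lapply(recs, as_tibble))
  }
  patients <- to_tbl(typed$Patient, empty_patients())
  if (anyDuplicated(patients$patient_id)) {
    abort("duplicate patient_id in Patient file")
  }
  clinical <- list(encounters = to_tbl(typed$Encounter, empty_encounters()),
                   conditions = to_tbl(typed$Condition, empty_conditions()),
                   immunizations = to_tbl(typed$Immunization,
                                          empty_immunizations()),
                   observations = to_tbl(typed$Observation,
                                         empty_observations()))
  # orphans: clinical records whose patient is absent go to rejects
  src <- c(encounters = "Encounter", conditions = "Condition",
           immunizations = "Immunization", observations = "Observation")
  for (tab in names(clinical)) {
    orphan <- !clinical[[tab]]$patient_id %in% patients$patient_id
    if (any(orphan)) {
      bad <- clinical[[tab]][orphan, ]
      rejects <- c(rejects, lapply(bad$patient_id, function(p) {
        list(file = src[[tab]], line = NA_integer_,
             reason = sprintf("unknown patient_id: %s", p))
      }))
      clinical[[tab]] <- clinical[[tab]][!orphan, ]
    }
  }
  rej <- if (length(rejects)) bind_rows(lapply(rejects, as_tibble)) else
    empty_rejects()
  new_bundle(patients = patients, encounters = clinical$encounters,
             conditions = clinical$conditions,
             immunizations = clinical$immunizations,
             observations = clinical$observations,
             passthrough = passthrough, rejects = rej)
}

# -- serializers ------------------------------------------------------------

fhir_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

serialize_patient <- function(r) {
  fhir_json(list(
    resourceType = "Patient", id = r$patient_id,
    name = list(list(text = r$name)), gender = r$sex,
    birthDate = format(r$birth_date),
    extension = list(
      list(url = US_CORE_RACE, valueString = r$race),
      list(url = US_CORE_ETHNICITY, valueString = r$ethnicity))))
}

serialize_encounter <- function(r) {
  fhir_json(list(
    resourceType = "Encounter", id = r$encounter_id,
    class = list(system = ACT_CODE_SYSTEM,
                 code = unname(FHIR_CLASS_BY_SETTING[r$care_setting])),
    subject = list(reference = paste0("Patient/", r$patient_id)),
    period = list(start = format(r$start_date), end = format(r$end_date))))
}

serialize_condition <- function(r) {
  x <- list(
    resourceType = "Condition", id = r$condition_id,
    subject = list(reference = paste0("Patient/", r$patient_id)),
    code = list(coding = list(list(system = r$system, code = r$code))),
    category = list(list(coding = list(list(code = r$diagnosis_role)))),
    onsetDateTime = format(r$onset_date))
  if (!is.na(r$encounter_id)) {
    x$encounter <- list(reference = paste0("Encounter/", r$encounter_id))
  }
  fhir_json(x)
}

serialize_immunization <- function(r) {
  fhir_json(list(
    resourceType = "Immunization", id = r$immunization_id, status = "completed",
    vaccineCode = list(coding = list(list(system = r$system, code = r$code))),
    patient = list(reference = paste0("Patient/", r$patient_id)),
    occurrenceDateTime = format(r$administration_date)))
}

serialize_observation <- function(r) {
  x <- list(
    resourceType = "Observation", id = r$observation_id, status = "final",
    code = list(coding = list(list(system = r$system, code = r$code))),
    subject = list(reference = paste0("Patient/", r$patient_id)),
    effectiveDateTime = format(r$effective_date))
  if (!is.na(r$value)) x$valueQuantity <- list(value = r$value)
  fhir_json(x)
}

#' Write an EHR bundle as FHIR R4 NDJSON
#'
#' One `<ResourceType>.ndjson` file per resource type present; records are
#' sorted by resource id so repeated writes of the same bundle are
#' byte-identical and diffable. Pass-through resources are emitted verbatim.
#'
#' @param bundle an `ehr_bundle`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the character vector of files written.
#' @export
write_bundle <- function(bundle, dir) {
  validate_bundle(bundle)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create directory: %s", dir))
  written <- character()
  emit <- function(type, lines) {
    path <- file.path(dir, paste0(type, ".ndjson"))
    writeLines(lines, path, useBytes = TRUE)
    written <<- c(written, path)
  }
  tabs <- list(
    Patient = list(bundle$patients, "patient_id", serialize_patient),
    Encounter = list(bundle$encounters, "encounter_id", serialize_encounter),
    Condition = list(bundle$conditions, "condition_id", serialize_condition),
    Immunization = list(bundle$immunizations, "immunization_id",
                        serialize_immunization),
    Observation = list(bundle$observations, "observation_id",
                       serialize_observation))
  for (type in names(tabs)) {
    tab <- tabs[[type]][[1]][order(tabs[[type]][[1]][[tabs[[type]][[2]]]]), ]
    lines <- vapply(seq_len(nrow(tab)),
                    function(i) tabs[[type]][[3]](tab[i, ]), character(1))
    emit(type, lines)
  }
  for (type in names(bundle$passthrough)) {
    lines <- bundle$passthrough[[type]]
    ids <- vapply(lines, function(l) {
      m <- regmatches(l, regexpr('"id"\\s*:\\s*"[^"]*"', l))
      if (length(m)) sub('.*:\\s*"', "", sub('"$', "", m)) else ""
    }, character(1), USE.NAMES = FALSE)
    emit(type, lines[order(ids)])
  }
  invisible(written)
}
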