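#' @title Exchange-style case retrieval
#' @description Simulates the health-information-exchange retrieval step
#'   that follows detection: each flagged case's demographics are matched
#'   against the patient registry, cases whose demographics match more than
#'   one registry patient are withheld for privacy (the multi-match
#'   exclusion), and a per-case validation payload is assembled with
#'   per-resource-type date windows — observations, diagnostic reports and
#'   document references restricted to the study period; conditions,
#'   encounters, immunizations, medication requests, procedures and
#'   allergies carried with full clinical history; locations, practitioners
#'   and medications included only when referenced by an included record.
#' @name exchange_retrieval
NULL

PAYLOAD_STUDY_PERIOD_TYPES <- c("DiagnosticReport", "DocumentReference")
PAYLOAD_LINKED_ONLY_TYPES <- c("Location", "Practitioner", "Medication")

#' Match case demographics against a patient registry
#'
#' Exact match on the normalized name key, birth date and sex.
#'
#' @param demographics list or one-row data frame with `name_key`,
#'   `birth_date`, `sex`.
#' @param registry patient tibble (e.g. `bundle$patients`).
#' @return List with `match_status` (`"unique"`, `"multiple"` or `"none"`),
#'   `matched_registry_ids`, and `reason` (`"incomplete demographics"` when
#'   a key field is missing, otherwise `NA`).
#' @export
match_patient <- function(demographics, registry) {
  d <- as.list(demographics)
  keys <- c("name_key", "birth_date", "sex")
  if (any(vapply(keys, function(k) is.null(d[[k]]) || is.na(d[[k]]),
                 logical(1)))) {
    return(list(match_status = "none", matched_registry_ids = character(),
                reason = "incomplete demographics"))
  }
  hit <- registry$name_key == d$name_key &
    registry$birth_date == as.Date(d$birth_date) & registry$sex == d$sex
  ids <- registry$patient_id[hit]
  status <- if (length(ids) == 0) "none" else if (length(ids) == 1) "unique"
  else "multiple"
  list(match_status = status, matched_registry_ids = ids,
       reason = NA_character_)
}

passthrough_date <- function(line) {
  m <- regmatches(line, regexpr(
    '"(effectiveDateTime|date|authoredOn|performedDateTime)"\\s*:\\s*"([0-9]{4}-[0-9]{2}-[0-9]{2})',
    line))
  if (!length(m)) return(as.Date(NA))
  as.Date(sub('.*"([0-9]{4}-[0-9]{2}-[0-9]{2})$', "\\1", m))
}

#' Assemble the validation payload for a retrieved case
#'
#' @param case one-row candidate tibble (from [detect()]).
#' @param bundle the registry-side `ehr_bundle`.
#' @param study_period `c(start, end)` dates bounding study-period-windowed
#'   resource types.
#' @return A `case_payload` list: `case_id`, `patient_id`, the typed record
#'   tables (observations restricted to the study period, the rest full
#'   history), and `passthrough` raw resources with their windows applied
#'   and linked-only types included only when referenced.
#' @export
assemble_payload <- function(case, bundle,
                             study_period = c(as.Date("2020-12-14"),
                                              as.Date("2023-04-28"))) {
  pid <- case$patient_id
  pat_tag <- paste0("Patient/", pid)
  payload <- list(
    case_id = pid, patient_id = pid,
    patients = bundle$patients[bundle$patients$patient_id == pid, ],
    encounters = bundle$encounters[bundle$encounters$patient_id == pid, ],
    conditions = bundle$conditions[bundle$conditions$patient_id == pid, ],
    immunizations =
      bundle$immunizations[bundle$immunizations$patient_id == pid, ],
    observations = bundle$observations[
      bundle$observations$patient_id == pid &
        bundle$observations$effective_date >= study_period[1] &
        bundle$observations$effective_date <= study_period[2], ])
  pt <- list()
  for (type in setdiff(names(bundle$passthrough),
                       PAYLOAD_LINKED_ONLY_TYPES)) {
    lines <- bundle$passthrough[[type]]
    lines <- lines[grepl(pat_tag, lines, fixed = TRUE)]
    if (type %in% PAYLOAD_STUDY_PERIOD_TYPES && length(lines)) {
      dates <- as.Date(vapply(lines, function(l) format(passthrough_date(l)),
                              character(1), USE.NAMES = FALSE))
      lines <- lines[is.na(dates) |
                       (dates >= study_period[1] & dates <= study_period[2])]
    }
    pt[[type]] <- lines
  }
  # linked-only resources: scan every included record for references
  corpus <- c(unlist(pt, use.names = FALSE))
  for (type in intersect(PAYLOAD_LINKED_ONLY_TYPES,
                         names(bundle$passthrough))) {
    refs <- unlist(regmatches(corpus,
                              gregexpr(paste0(type, "/[A-Za-z0-9.-]+"),
                                       corpus)))
    ids <- unique(sub(paste0("^", type, "/"), "", refs))
    lines <- bundle$passthrough[[type]]
    keep <- vapply(lines, function(l) {
      m <- regmatches(l, regexpr('"id"\\s*:\\s*"[^"]*"', l))
      length(m) && sub('.*:\\s*"', "", sub('"$', "", m)) %in% ids
    }, logical(1), USE.NAMES = FALSE)
    pt[[type]] <- lines[keep]
  }
  payload$passthrough <- pt
  structure(payload, class = "case_payload")
}

#' Retrieve validation payloads for all flagged cases
#'
#' Applies demographic matching then payload assembly; cases matching
#' multiple registry patients (or none) are excluded and accounted for
#' separately.
#'
#' @param candidates candidate tibble from [detect()].
#' @param bundle the registry-side `ehr_bundle`.
#' @param study_period `c(start, end)` dates.
#' @return List with `payloads` (list of `case_payload`), `attrition`
#'   (`stage, unit, entering, surviving` for the retrieval stage), and
#'   `exclusions` (`patient_id`, `reason`).
#' @export
retrieve_all <- function(candidates, bundle,
                         study_period = c(as.Date("2020-12-14"),
                                          as.Date("2023-04-28"))) {
  payloads <- list()
  excl <- list()
  for (i in seq_len(nrow(candidates))) {
    case <- candidates[i, ]
    m <- match_patient(case[, c("name_key", "birth_date", "sex")],
                       bundle$patients)
    if (m$match_status == "unique") {
      payloads[[length(payloads) + 1L]] <-
        assemble_payload(case, bundle, study_period)
    } else {
      reason <- if (!is.na(m$reason)) m$reason
      else if (m$match_status == "multiple") "multiple demographic matches"
      else "no demographic match"
      excl[[length(excl) + 1L]] <-
        tibble(patient_id = case$patient_id, reason = reason)
    }
  }
  exclusions <- if (length(excl)) bind_rows(excl) else
    tibble(patient_id = character(), reason = character())
  attrition <- tibble(stage = "retrieval_match", unit = "cases",
                      entering = nrow(candidates),
                      surviving = length(payloads))
  list(payloads = payloads, attrition = attrition, exclusions = exclusions)
}
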