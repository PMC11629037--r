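#' @title Coded value sets
#' @description Value sets are lists of codings (code system URI + code)
#'   with a role that determines where the phenotype uses them:
#'   `target_diagnosis` (the adverse-event diagnosis family),
#'   `supporting_evidence` (laboratory/workup observations), and
#'   `exposure_vaccine` (qualifying vaccine codes). Matching is exact,
#'   case-sensitive `(system, code)` equality after trimming; entries flagged
#'   `prefix` match any code starting with the entry code, which is how
#'   ICD-10 families such as I40.* are usually expressed.
#' @name valuesets
NULL

VALUESET_ROLES <- c("target_diagnosis", "supporting_evidence",
                    "exposure_vaccine")

ICD10CM <- "http://hl7.org/fhir/sid/icd-10-cm"
LOINC   <- "http://loinc.org"
CVX     <- "http://hl7.org/fhir/sid/cvx"

#' Load value sets from a CSV or YAML configuration file
#'
#' CSV needs columns `name, role, system, code, prefix, description`
#' (`prefix` logical; absent column means all-exact). YAML is a list of sets,
#' each with `name`, `role`, `description` and an `entries` list of
#' `{system, code, prefix}`.
#'
#' @param path configuration file; extension decides the format.
#' @return A tibble with one row per entry and columns
#'   `name, role, system, code, prefix, description`.
#' @export
load_valuesets <- function(path) {
  if (!file.exists(path)) abort(sprintf("value-set file not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    cfg <- yaml::read_yaml(path)
    vs <- bind_rows(lapply(cfg, function(set) {
      entries <- bind_rows(lapply(set$entries, function(e) {
        tibble(system = e$system, code = as.character(e$code),
               prefix = isTRUE(e$prefix))
      }))
      mutate(entries, name = set$name, role = set$role,
             description = set$description %||% "")
    }))
  } else {
    raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!"prefix" %in% names(raw)) raw$prefix <- "FALSE"
    if (!"description" %in% names(raw)) raw$description <- ""
    vs <- as_tibble(raw)
    vs$prefix <- toupper(trimws(vs$prefix)) %in% c("TRUE", "T", "1", "YES")
  }
  vs <- vs[, c("name", "role", "system", "code", "prefix", "description")]
  vs$system <- trimws(vs$system)
  vs$code <- trimws(vs$code)
  bad_role <- setdiff(unique(vs$role), VALUESET_ROLES)
  if (length(bad_role)) {
    off <- unique(vs$name[vs$role %in% bad_role])
    abort(sprintf("unknown value-set role '%s' in set '%s'",
                  bad_role[[1]], off[[1]]))
  }
  dup <- vs[duplicated(vs[, c("name", "system", "code")]), ]
  if (nrow(dup)) {
    abort(sprintf("duplicate entry (%s, %s) in value set '%s'",
                  dup$system[[1]], dup$code[[1]], dup$name[[1]]))
  }
  missing_role <- setdiff(VALUESET_ROLES, unique(vs$role))
  if (length(missing_role)) {
    abort(sprintf("configuration defines no value set with role '%s'",
                  missing_role[[1]]))
  }
  vs
}

#' Default value sets shipped with the package
#'
#' Editable stand-in code lists for the myocarditis/pericarditis phenotype:
#' ICD-10-CM myocarditis/pericarditis families for the target diagnosis,
#' LOINC troponin/CK-MB assays as supporting evidence, and CVX COVID-19
#' vaccine codes for the exposure. Intended as a documented starting point;
#' production deployments supply their own curated lists via
#' [load_valuesets()].
#'
#' @return Value-set tibble (see [load_valuesets()]).
#' @export
default_valuesets <- function() {
  load_valuesets(system.file("extdata", "valuesets.csv",
                             package = "phenoval", mustWork = TRUE))
}

#' Restrict a value-set table to one role
#' @param valuesets value-set tibble.
#' @param role one of `r paste(VALUESET_ROLES, collapse = ", ")`.
#' @param required error if the result is empty (default TRUE).
#' @return The rows of `valuesets` with the requested role.
#' @export
valueset_for_role <- function(valuesets, role, required = TRUE) {
  role <- match.arg(role, VALUESET_ROLES)
  out <- valuesets[valuesets$role == role, ]
  if (required && !nrow(out)) {
    abort(sprintf("no value set with required role '%s'", role))
  }
  out
}

#' Test codings for membership in a value set
#'
#' Vectorized over parallel `system`/`code` vectors. A coding is a member
#' iff some entry has the same system and either an exact (case-sensitive)
#' code match or, for `prefix` entries, the entry code is a leading
#' substring of the coding's code.
#'
#' @param system,code character vectors of equal length.
#' @param valueset value-set tibble (typically one role's rows).
#' @return Logical vector.
#' @export
coding_in_valueset <- function(system, code, valueset) {
  system <- trimws(system); code <- trimws(code)
  hit <- rep(FALSE, length(code))
  exact <- valueset[!valueset$prefix, ]
  if (nrow(exact)) {
    hit <- paste0(system, "\r", code) %in%
      paste0(exact$system, "\r", exact$code)
  }
  pre <- valueset[valueset$prefix, ]
  for (i in seq_len(nrow(pre))) {
    hit <- hit | (system == pre$system[[i]] & startsWith(code, pre$code[[i]]))
  }
  hit
}
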