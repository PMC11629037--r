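#' @title Synthetic EHR cohort generator
#' @description Generates seeded FHIR-style EHR bundles with latent ground
#'   truth so every pipeline stage can be exercised without patient data.
#'   Each planted case category carries exactly the temporal and care-setting
#'   structure its name implies, so an independent scan of the generated
#'   records can verify which detection stage should pass or exclude it:
#'   \describe{
#'     \item{true_in_window}{vaccination at `v`, inpatient target diagnosis
#'       at `v + U`, `U ~ Uniform{0..42}`, supporting evidence within a week,
#'       clean 365-day lookback.}
#'     \item{out_of_window}{as above with `U ~ Uniform{43..120}`.}
#'     \item{prevalent}{in-window structure plus a prior qualifying
#'       diagnosis 30-364 days before the index.}
#'     \item{outpatient_only}{in-window structure but the diagnosis occurs
#'       only in a non-inpatient setting.}
#'     \item{unvaccinated}{inpatient incident diagnosis with no qualifying
#'       vaccine exposure (some receive a non-COVID vaccine).}
#'     \item{duplicate_demographics}{a detectable case whose normalized
#'       name, birth date and sex are cloned onto a second patient, tripping
#'       the retrieval multi-match exclusion.}
#'     \item{background}{encounters, non-target diagnoses and vaccinations
#'       but no target diagnosis.}
#'   }
#' @name synthetic_cohort
NULL

# Table-style demographic marginals of an academic health system's patient
# population (proportions over patients).
default_demographic_marginals <- function() {
  list(
    age = c("<5" = 0.0436, "5-17" = 0.0558, "18-24" = 0.0661,
            "25-44" = 0.3097, "45-64" = 0.2808, ">65" = 0.2420),
    sex = c(male = 0.4572, female = 0.5406, other = 0.0022),
    race = c(white = 0.6058, black = 0.1050, asian_pacific_islander = 0.0900,
             american_indian_alaska_native = 0.0030, other = 0.0833,
             unknown = 0.1053, declined = 0.0076),
    ethnicity = c(hispanic = 0.1433, non_hispanic = 0.7313,
                  unknown = 0.1254))
}

AGE_BIN_YEARS <- list("<5" = c(0, 5), "5-17" = c(5, 18), "18-24" = c(18, 25),
                      "25-44" = c(25, 45), "45-64" = c(45, 65),
                      ">65" = c(65, 90))

FIRST_NAMES <- c("olivia", "liam", "emma", "noah", "amelia", "oliver",
                 "sophia", "elijah", "charlotte", "james", "ava", "william",
                 "isabella", "benjamin", "mia", "lucas", "evelyn", "henry",
                 "harper", "theodore", "luna", "jack", "camila", "levi",
                 "gianna", "alexander", "elizabeth", "jackson", "eleanor",
                 "mateo", "ella", "daniel", "abigail", "michael", "sofia",
                 "mason", "avery", "sebastian", "scarlett", "ethan", "emily",
                 "logan", "aria", "owen", "penelope", "samuel", "chloe",
                 "jacob", "layla", "asher")
LAST_NAMES <- c("smith", "johnson", "williams", "brown", "jones", "garcia",
                "miller", "davis", "rodriguez", "martinez", "hernandez",
                "lopez", "gonzalez", "wilson", "anderson", "thomas", "taylor",
                "moore", "jackson", "martin", "lee", "perez", "thompson",
                "white", "harris", "sanchez", "clark", "ramirez", "lewis",
                "robinson", "walker", "young", "allen", "king", "wright",
                "scott", "torres", "nguyen", "hill", "flores", "green",
                "adams", "nelson", "baker", "hall", "rivera", "campbell",
                "mitchell", "carter", "roberts")

TARGET_DX_POOL <- c("I40.0", "I40.1", "I40.8", "I40.9", "I41", "I51.4",
                    "I30.0", "I30.1", "I30.9", "I31.9", "I32")
EVIDENCE_POOL <- c("6598-7", "10839-9", "42757-5", "49563-0", "13969-1")
VACCINE_POOL <- c("207", "208", "211", "212")
BACKGROUND_DX_POOL <- c("I10", "E11.9", "J06.9", "M54.5", "K21.9", "N39.0")
NONCOVID_VACCINE <- "140" # seasonal influenza, outside the exposure set

PLANTED_CATEGORIES <- c("true_in_window", "out_of_window", "prevalent",
                        "outpatient_only", "unvaccinated",
                        "duplicate_demographics")

#' Specify a synthetic cohort
#'
#' @param n_patients total number of patients.
#' @param study_start,study_end study period (defaults 2020-12-14 /
#'   2023-04-28).
#' @param observation_start start of available history (default 2019-12-14,
#'   giving every in-study index date a full year of lookback).
#' @param demographic_marginals list of named proportion vectors for
#'   `age`, `sex`, `race`, `ethnicity`.
#' @param vaccination_coverage probability that a background patient aged 5+
#'   receives a COVID-19 vaccination during the study period.
#' @param n_true_cases,n_out_of_window_cases,n_prevalent_cases,n_outpatient_cases,n_unvaccinated_cases,n_duplicate_demographic_cases
#'   planted counts per category (see [synthetic_cohort]). Each duplicate
#'   case consumes one background patient as its demographic clone.
#' @param insufficient_evidence_rate probability that a detectable case's
#'   supporting documentation is withheld from the retrieval payload, so the
#'   case is flagged but cannot be confirmed on review.
#' @param truth_ppv probability that a detectable case's latent label is a
#'   true adverse event.
#' @param seed integer RNG seed; the same spec and seed reproduce the bundle
#'   byte for byte.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 200,
                        study_start = as.Date("2020-12-14"),
                        study_end = as.Date("2023-04-28"),
                        observation_start = as.Date("2019-12-14"),
                        demographic_marginals = default_demographic_marginals(),
                        vaccination_coverage = 0.6,
                        n_true_cases = 10, n_out_of_window_cases = 4,
                        n_prevalent_cases = 4, n_outpatient_cases = 4,
                        n_unvaccinated_cases = 4,
                        n_duplicate_demographic_cases = 2,
                        insufficient_evidence_rate = 0.077,
                        truth_ppv = 0.583, seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               study_start = as.Date(study_start),
               study_end = as.Date(study_end),
               observation_start = as.Date(observation_start),
               demographic_marginals = demographic_marginals,
               vaccination_coverage = vaccination_coverage,
               n_true_cases = as.integer(n_true_cases),
               n_out_of_window_cases = as.integer(n_out_of_window_cases),
               n_prevalent_cases = as.integer(n_prevalent_cases),
               n_outpatient_cases = as.integer(n_outpatient_cases),
               n_unvaccinated_cases = as.integer(n_unvaccinated_cases),
               n_duplicate_demographic_cases =
                 as.integer(n_duplicate_demographic_cases),
               insufficient_evidence_rate = insufficient_evidence_rate,
               truth_ppv = truth_ppv, seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  props <- c(spec$vaccination_coverage, spec$insufficient_evidence_rate,
             spec$truth_ppv,
             unlist(spec$demographic_marginals, use.names = FALSE))
  if (any(props < 0 | props > 1)) abort("proportions must lie in [0, 1]")
  planted <- spec$n_true_cases + spec$n_out_of_window_cases +
    spec$n_prevalent_cases + spec$n_outpatient_cases +
    spec$n_unvaccinated_cases + spec$n_duplicate_demographic_cases
  if (planted + spec$n_duplicate_demographic_cases > spec$n_patients) {
    abort("infeasible spec: planted cases (plus demographic clones) exceed n_patients")
  }
  if (spec$study_end < spec$study_start ||
      spec$observation_start > spec$study_start) {
    abort("invalid study/observation dates")
  }
  invisible(spec)
}

with_cohort_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

rint <- function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1L))

draw_demographics <- function(n, spec, adult) {
  m <- spec$demographic_marginals
  sex <- sample(names(m$sex), n, TRUE, prob = m$sex)
  race <- sample(names(m$race), n, TRUE, prob = m$race)
  ethnicity <- sample(names(m$ethnicity), n, TRUE, prob = m$ethnicity)
  bins <- names(m$age)
  adult_bins <- bins[vapply(bins, function(b) AGE_BIN_YEARS[[b]][1] >= 18,
                            logical(1))]
  bin <- character(n)
  bin[!adult] <- sample(bins, sum(!adult), TRUE, prob = m$age)
  # planted adverse-event cases are drawn from adult strata so that every
  # planted historical record postdates the patient's birth
  bin[adult] <- sample(adult_bins, sum(adult), TRUE,
                       prob = m$age[adult_bins])
  lo <- vapply(bin, function(b) AGE_BIN_YEARS[[b]][1], numeric(1))
  hi <- vapply(bin, function(b) AGE_BIN_YEARS[[b]][2], numeric(1))
  age_days <- rint(n, floor(lo * 365.25), floor(hi * 365.25) - 1L)
  name <- paste(sample(FIRST_NAMES, n, TRUE), sample(LAST_NAMES, n, TRUE))
  tibble(name = name, name_key = normalize_name(name),
         birth_date = spec$study_start - age_days, sex = sex, race = race,
         ethnicity = ethnicity, age_bin = bin)
}

#' Generate a synthetic EHR cohort with truth labels
#'
#' @param spec a [cohort_spec()].
#' @return A list with `bundle` (an `ehr_bundle`) and `truth`, a tibble with
#'   one row per patient: `patient_id`, `is_true_ae`, `planted_category`,
#'   `evidence_complete`, and `fixed_class` (NA except in deterministic
#'   fixtures, where it pins the adjudicated classification).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_cohort_seed(spec$seed, {
    n <- spec$n_patients
    counts <- c(true_in_window = spec$n_true_cases,
                out_of_window = spec$n_out_of_window_cases,
                prevalent = spec$n_prevalent_cases,
                outpatient_only = spec$n_outpatient_cases,
                unvaccinated = spec$n_unvaccinated_cases,
                duplicate_demographics = spec$n_duplicate_demographic_cases)
    category <- c(rep(names(counts), counts),
                  rep("background", n - sum(counts)))
    planted <- category != "background"

    demog <- draw_demographics(n, spec, adult = planted)
    # demographic keys are unique except for deliberate clones
    repeat {
      key <- paste(demog$name_key, demog$birth_date, demog$sex)
      dup <- duplicated(key)
      if (!any(dup)) break
      k <- sum(dup)
      nm <- paste(sample(FIRST_NAMES, k, TRUE), sample(LAST_NAMES, k, TRUE))
      demog$name[dup] <- nm
      demog$name_key[dup] <- normalize_name(nm)
    }
    patients <- tibble(patient_id = sprintf("P%06d", seq_len(n))) %>%
      dplyr::bind_cols(demog[, c("name", "name_key", "birth_date", "sex",
                                 "race", "ethnicity")])

    # clone demographics of duplicate-category cases onto the last
    # background patients (distinct patient_id, identical matching key)
    dup_idx <- which(category == "duplicate_demographics")
    if (length(dup_idx)) {
      host_idx <- utils::tail(which(category == "background"),
                              length(dup_idx))
      patients[host_idx, c("name", "name_key", "birth_date", "sex")] <-
        patients[dup_idx, c("name", "name_key", "birth_date", "sex")]
    }

    study_days <- as.integer(spec$study_end - spec$study_start)
    counter <- new.env()
    next_ids <- function(prefix, k) {
      cur <- get0(prefix, envir = counter, inherits = FALSE,
                  ifnotfound = 0L)
      assign(prefix, cur + k, envir = counter)
      if (k) sprintf("%s%07d", prefix, cur + seq_len(k)) else character()
    }
    enc <- list(); cond <- list(); imm <- list(); obs <- list()

    # -- planted adverse-event structures -----------------------------------
    plant <- function(idx, off_lo, off_hi, setting, exposure) {
      k <- length(idx)
      if (!k) return(invisible())
      pid <- patients$patient_id[idx]
      v <- spec$study_start + rint(k, 0L, study_days - 121L)
      d <- v + rint(k, off_lo, off_hi)
      eid <- next_ids("E", k)
      enc[[length(enc) + 1L]] <<- tibble(
        encounter_id = eid, patient_id = pid, care_setting = setting,
        start_date = d, end_date = d + rint(k, 1L, 6L))
      cond[[length(cond) + 1L]] <<- tibble(
        condition_id = next_ids("C", k), patient_id = pid,
        encounter_id = eid, system = ICD10CM,
        code = sample(TARGET_DX_POOL, k, TRUE), onset_date = d,
        diagnosis_role = "final")
      # a same-code admitting-role record on some cases; filtered out of
      # index selection, never changes the detected set
      adm <- runif(k) < 0.3
      if (any(adm)) {
        cond[[length(cond) + 1L]] <<- tibble(
          condition_id = next_ids("C", sum(adm)), patient_id = pid[adm],
          encounter_id = eid[adm], system = ICD10CM,
          code = sample(TARGET_DX_POOL, sum(adm), TRUE),
          onset_date = d[adm], diagnosis_role = "admitting")
      }
      obs[[length(obs) + 1L]] <<- tibble(
        observation_id = next_ids("O", k), patient_id = pid,
        system = LOINC, code = sample(EVIDENCE_POOL, k, TRUE),
        effective_date = d + rint(k, -2L, 2L),
        value = round(runif(k, 0.05, 12), 3))
      if (exposure) {
        imm[[length(imm) + 1L]] <<- tibble(
          immunization_id = next_ids("I", k), patient_id = pid,
          system = CVX, code = sample(VACCINE_POOL, k, TRUE),
          administration_date = v)
        # earlier primary-series dose for some (larger offset; the engine
        # must pick the most recent in-window dose)
        prior <- runif(k) < 0.4 & v - 150L >= spec$study_start
        if (any(prior)) {
          imm[[length(imm) + 1L]] <<- tibble(
            immunization_id = next_ids("I", sum(prior)),
            patient_id = pid[prior], system = CVX,
            code = sample(VACCINE_POOL, sum(prior), TRUE),
            administration_date = v[prior] - 150L)
        }
        # post-diagnosis booster for some (negative offset, never qualifies)
        post <- runif(k) < 0.2 & d + 30L <= spec$study_end
        if (any(post)) {
          imm[[length(imm) + 1L]] <<- tibble(
            immunization_id = next_ids("I", sum(post)),
            patient_id = pid[post], system = CVX,
            code = sample(VACCINE_POOL, sum(post), TRUE),
            administration_date = d[post] + rint(sum(post), 10L, 30L))
        }
      }
      invisible(d)
    }

    d_true <- plant(which(category == "true_in_window"), 0L, 42L,
                    "inpatient", TRUE)
    plant(which(category == "out_of_window"), 43L, 120L, "inpatient", TRUE)
    d_prev <- plant(which(category == "prevalent"), 0L, 42L, "inpatient",
                    TRUE)
    prev_idx <- which(category == "prevalent")
    if (length(prev_idx)) {
      k <- length(prev_idx)
      cond[[length(cond) + 1L]] <- tibble(
        condition_id = next_ids("C", k),
        patient_id = patients$patient_id[prev_idx],
        encounter_id = NA_character_, system = ICD10CM,
        code = sample(TARGET_DX_POOL, k, TRUE),
        onset_date = d_prev - rint(k, 30L, 364L), diagnosis_role = "final")
    }
    plant(which(category == "outpatient_only"), 0L, 42L, "outpatient", TRUE)
    unvax_idx <- which(category == "unvaccinated")
    plant(unvax_idx, 0L, 42L, "inpatient", FALSE)
    if (length(unvax_idx)) {
      flu <- runif(length(unvax_idx)) < 0.5
      if (any(flu)) {
        imm[[length(imm) + 1L]] <- tibble(
          immunization_id = next_ids("I", sum(flu)),
          patient_id = patients$patient_id[unvax_idx][flu], system = CVX,
          code = NONCOVID_VACCINE,
          administration_date = spec$study_start +
            rint(sum(flu), 0L, study_days))
      }
    }
    plant(which(category == "duplicate_demographics"), 0L, 42L, "inpatient",
          TRUE)

    # -- background care ----------------------------------------------------
    bg_idx <- which(category == "background")
    if (length(bg_idx)) {
      n_enc <- rint(length(bg_idx), 1L, 3L)
      row <- rep(bg_idx, n_enc)
      k <- length(row)
      lo <- pmax(spec$observation_start,
                 patients$birth_date[row] + 1L)
      start <- lo + floor(runif(k) *
                            (as.integer(spec$study_end - lo) + 1L))
      eid <- next_ids("E", k)
      enc[[length(enc) + 1L]] <- tibble(
        encounter_id = eid, patient_id = patients$patient_id[row],
        care_setting = sample(c("inpatient", "outpatient", "emergency"), k,
                              TRUE, prob = c(0.15, 0.75, 0.10)),
        start_date = start, end_date = start + rint(k, 0L, 4L))
      with_dx <- runif(k) < 0.6
      if (any(with_dx)) {
        cond[[length(cond) + 1L]] <- tibble(
          condition_id = next_ids("C", sum(with_dx)),
          patient_id = patients$patient_id[row][with_dx],
          encounter_id = eid[with_dx], system = ICD10CM,
          code = sample(BACKGROUND_DX_POOL, sum(with_dx), TRUE),
          onset_date = start[with_dx], diagnosis_role = "final")
      }
      with_obs <- runif(k) < 0.3
      if (any(with_obs)) {
        obs[[length(obs) + 1L]] <- tibble(
          observation_id = next_ids("O", sum(with_obs)),
          patient_id = patients$patient_id[row][with_obs], system = LOINC,
          code = "2345-7", effective_date = start[with_obs],
          value = round(runif(sum(with_obs), 70, 120), 1))
      }
      eligible <- patients$birth_date[bg_idx] <=
        spec$study_start - round(5 * 365.25)
      vax <- runif(length(bg_idx)) < spec$vaccination_coverage & eligible
      if (any(vax)) {
        imm[[length(imm) + 1L]] <- tibble(
          immunization_id = next_ids("I", sum(vax)),
          patient_id = patients$patient_id[bg_idx][vax], system = CVX,
          code = sample(VACCINE_POOL, sum(vax), TRUE),
          administration_date = spec$study_start +
            rint(sum(vax), 0L, study_days))
      }
    }

    # -- latent truth -------------------------------------------------------
    detectable <- category %in% c("true_in_window", "duplicate_demographics")
    truth <- tibble(
      patient_id = patients$patient_id,
      planted_category = category,
      is_true_ae = detectable & runif(n) < spec$truth_ppv,
      evidence_complete = !detectable |
        runif(n) >= spec$insufficient_evidence_rate,
      fixed_class = NA_character_)

    # pass-through documentation: a diagnostic report for each detectable
    # case whose evidence is complete, plus practitioner stubs (one
    # referenced by reports, one never referenced)
    dr_idx <- which(detectable & truth$evidence_complete)
    passthrough <- list(
      DiagnosticReport = vapply(seq_along(dr_idx), function(j) {
        i <- dr_idx[[j]]
        sprintf(paste0('{"resourceType":"DiagnosticReport","id":"DR%07d",',
                       '"subject":{"reference":"Patient/%s"},',
                       '"effectiveDateTime":"%s",',
                       '"performer":[{"reference":"Practitioner/PR0000001"}]}'),
                j, patients$patient_id[[i]],
                format(if (category[[i]] == "true_in_window") {
                  d_true[[match(i, which(category == "true_in_window"))]]
                } else spec$study_start + 30L))
      }, character(1)),
      Practitioner = c(
        '{"resourceType":"Practitioner","id":"PR0000001","name":[{"text":"attending cardiologist"}]}',
        '{"resourceType":"Practitioner","id":"PR0000002","name":[{"text":"unlinked clinician"}]}'))

    bind_or <- function(lst, empty) if (length(lst)) bind_rows(lst) else empty
    bundle <- new_bundle(
      patients = patients[, c("patient_id", "name", "name_key", "birth_date",
                              "sex", "race", "ethnicity")],
      encounters = bind_or(enc, empty_encounters()),
      conditions = bind_or(cond, empty_conditions()),
      immunizations = bind_or(imm, empty_immunizations()),
      observations = bind_or(obs, empty_observations()),
      passthrough = passthrough)
    list(bundle = bundle, truth = truth)
  })
}

#' Write a generated cohort to disk
#'
#' Writes the bundle as FHIR NDJSON plus `truth_labels.csv`.
#'
#' @param cohort result of [generate_cohort()] or [consort_scenario()].
#' @param dir output directory.
#' @return Invisibly, the files written.
#' @export
write_cohort <- function(cohort, dir) {
  files <- write_bundle(cohort$bundle, dir)
  tl <- file.path(dir, "truth_labels.csv")
  write.csv(cohort$truth, tl, row.names = FALSE)
  invisible(c(files, tl))
}

#' Read truth labels written by [write_cohort()]
#' @param path `truth_labels.csv` file.
#' @return Truth tibble.
#' @export
read_truth_labels <- function(path) {
  tl <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  tl$is_true_ae <- as.logical(tl$is_true_ae)
  tl$evidence_complete <- as.logical(tl$evidence_complete)
  tl$fixed_class <- as.character(tl$fixed_class)
  tl
}

#' Deterministic validation-study scenario
#'
#' A fixed synthetic cohort wired so the full pipeline — detection,
#' retrieval, adjudication — produces a known attrition chain: 30 flagged
#' cases, 4 excluded as demographic multi-matches, 26 retrieved, 2 marked
#' insufficient evidence, and 24 adjudicated as 3 definite / 11 probable /
#' 0 possible / 10 doubtful (14 true positives). Classifications are pinned
#' via the truth table's `fixed_class` column, so the scenario is fully
#' deterministic regardless of reviewer-simulation parameters.
#'
#' @return A list with `bundle` and `truth` (see [generate_cohort()]).
#' @export
consort_scenario <- function() {
  spec <- cohort_spec(n_patients = 120, n_true_cases = 26,
                      n_out_of_window_cases = 4, n_prevalent_cases = 4,
                      n_outpatient_cases = 4, n_unvaccinated_cases = 4,
                      n_duplicate_demographic_cases = 4,
                      insufficient_evidence_rate = 0, truth_ppv = 0,
                      seed = 20201214L)
  cohort <- generate_cohort(spec)
  truth <- cohort$truth
  true_ids <- sort(truth$patient_id[truth$planted_category ==
                                      "true_in_window"])
  insufficient_ids <- true_ids[1:2]
  reviewed_ids <- true_ids[-(1:2)]
  truth$evidence_complete[truth$patient_id %in% insufficient_ids] <- FALSE
  cls <- rep(c("definite", "probable", "doubtful"), c(3, 11, 10))
  truth$fixed_class[match(reviewed_ids, truth$patient_id)] <- cls
  truth$is_true_ae <- !is.na(truth$fixed_class) &
    truth$fixed_class %in% c("definite", "probable")
  # withhold the supporting documentation of the insufficient-evidence cases
  keep <- !grepl(paste(paste0("Patient/", insufficient_ids), collapse = "|"),
                 cohort$bundle$passthrough$DiagnosticReport)
  cohort$bundle$passthrough$DiagnosticReport <-
    cohort$bundle$passthrough$DiagnosticReport[keep]
  cohort$truth <- truth
  cohort
}
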