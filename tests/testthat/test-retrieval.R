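test_that("demographic matching distinguishes unique, multiple and none", {
  reg <- mini_bundle()$patients
  d <- list(name_key = "ada park", birth_date = as.Date("1980-01-01"),
            sex = "female")
  expect_equal(match_patient(d, reg)$match_status, "unique")
  expect_equal(match_patient(d, reg)$matched_registry_ids, "P1")
  # clone Ada's key onto another record: both match, neither unique
  reg2 <- reg
  reg2[2, c("name_key", "birth_date", "sex")] <- reg[1, c("name_key",
                                                          "birth_date",
                                                          "sex")]
  m <- match_patient(d, reg2)
  expect_equal(m$match_status, "multiple")
  expect_setequal(m$matched_registry_ids, c("P1", "P2"))
  expect_equal(match_patient(list(name_key = "nobody here",
                                  birth_date = as.Date("1999-01-01"),
                                  sex = "male"), reg)$match_status, "none")
  m3 <- match_patient(list(name_key = "ada park",
                           birth_date = as.Date(NA), sex = "female"), reg)
  expect_equal(m3$match_status, "none")
  expect_equal(m3$reason, "incomplete demographics")
})

test_that("multi-match exclusion is symmetric: clones block each other", {
  cohort <- generate_cohort(cohort_spec(n_patients = 60, n_true_cases = 3,
                                        n_duplicate_demographic_cases = 2,
                                        seed = 31))
  pats <- cohort$bundle$patients
  dups <- cohort$truth$patient_id[cohort$truth$planted_category ==
                                    "duplicate_demographics"]
  for (pid in dups) {
    row <- pats[pats$patient_id == pid, ]
    m <- match_patient(row[, c("name_key", "birth_date", "sex")], pats)
    expect_equal(m$match_status, "multiple")
    # the clone is equally unretrievable
    other <- setdiff(m$matched_registry_ids, pid)
    mo <- match_patient(pats[pats$patient_id == other,
                             c("name_key", "birth_date", "sex")], pats)
    expect_equal(mo$match_status, "multiple")
  }
})

test_that("payload windows follow the per-resource-type rules", {
  b <- mini_bundle()
  # pre-study observation and condition for the case patient
  b$observations <- dplyr::bind_rows(b$observations, tibble::tibble(
    observation_id = "O9", patient_id = "P1", system = "http://loinc.org",
    code = "2345-7", effective_date = as.Date("2019-06-01"), value = 90))
  b$conditions <- dplyr::bind_rows(b$conditions, tibble::tibble(
    condition_id = "C9", patient_id = "P1", encounter_id = NA_character_,
    system = "http://hl7.org/fhir/sid/icd-10-cm", code = "J06.9",
    onset_date = as.Date("2019-06-01"), diagnosis_role = "final"))
  b$passthrough <- list(
    DiagnosticReport = c(
      '{"resourceType":"DiagnosticReport","id":"DR1","subject":{"reference":"Patient/P1"},"effectiveDateTime":"2021-03-16","performer":[{"reference":"Practitioner/PRX"}]}',
      '{"resourceType":"DiagnosticReport","id":"DR2","subject":{"reference":"Patient/P1"},"effectiveDateTime":"2019-06-01"}'),
    MedicationRequest = c(
      '{"resourceType":"MedicationRequest","id":"M1","subject":{"reference":"Patient/P1"},"authoredOn":"2019-06-01"}'),
    Practitioner = c(
      '{"resourceType":"Practitioner","id":"PRX","name":[{"text":"dr a"}]}',
      '{"resourceType":"Practitioner","id":"PRY","name":[{"text":"dr b"}]}'))
  cand <- detect(b, default_valuesets())$candidates
  pay <- assemble_payload(cand[1, ], b)
  # observations clipped to the study period; conditions full history
  expect_false("O9" %in% pay$observations$observation_id)
  expect_true("O1" %in% pay$observations$observation_id)
  expect_true("C9" %in% pay$conditions$condition_id)
  # study-period window applies to diagnostic reports
  expect_length(grep('"id":"DR1"', pay$passthrough$DiagnosticReport), 1)
  expect_length(grep('"id":"DR2"', pay$passthrough$DiagnosticReport), 0)
  # full-history types are not windowed
  expect_length(pay$passthrough$MedicationRequest, 1)
  # linked-only: PRX is referenced by DR1, PRY by nothing
  expect_length(grep('"id":"PRX"', pay$passthrough$Practitioner), 1)
  expect_length(grep('"id":"PRY"', pay$passthrough$Practitioner), 0)
})

test_that("payload records all satisfy their window rule on generated cohorts", {
  cohort <- generate_cohort(cohort_spec(n_patients = 80, n_true_cases = 6,
                                        seed = 17))
  res <- detect(cohort$bundle, default_valuesets())
  ret <- retrieve_all(res$candidates, cohort$bundle)
  expect_gt(length(ret$payloads), 0)
  sp <- c(as.Date("2020-12-14"), as.Date("2023-04-28"))
  for (pay in ret$payloads) {
    expect_true(all(pay$observations$effective_date >= sp[1] &
                      pay$observations$effective_date <= sp[2]))
    expect_true(all(pay$conditions$patient_id == pay$patient_id))
    for (line in pay$passthrough$DiagnosticReport) {
      expect_match(line, pay$patient_id, fixed = TRUE)
    }
  }
})

test_that("retrieval attrition separates multi-match exclusions", {
  cohort <- generate_cohort(cohort_spec(n_patients = 80, n_true_cases = 5,
                                        n_duplicate_demographic_cases = 3,
                                        seed = 23))
  res <- detect(cohort$bundle, default_valuesets())
  ret <- retrieve_all(res$candidates, cohort$bundle)
  expect_equal(nrow(res$candidates), 8)
  expect_equal(length(ret$payloads), 5)
  expect_equal(sum(ret$exclusions$reason == "multiple demographic matches"),
               3)
  # with no duplicates planted, payload count equals candidate count
  cohort2 <- generate_cohort(cohort_spec(n_patients = 80, n_true_cases = 5,
                                         n_duplicate_demographic_cases = 0,
                                         seed = 23))
  res2 <- detect(cohort2$bundle, default_valuesets())
  ret2 <- retrieve_all(res2$candidates, cohort2$bundle)
  expect_equal(length(ret2$payloads), nrow(res2$candidates))
  # worst case: clone every candidate's demographics -> nothing retrievable
  b3 <- cohort2$bundle
  cand_ids <- res2$candidates$patient_id
  hosts <- setdiff(b3$patients$patient_id, cand_ids)[seq_along(cand_ids)]
  b3$patients[match(hosts, b3$patients$patient_id),
              c("name_key", "birth_date", "sex")] <-
    b3$patients[match(cand_ids, b3$patients$patient_id),
                c("name_key", "birth_date", "sex")]
  ret3 <- retrieve_all(res2$candidates, b3)
  expect_equal(length(ret3$payloads), 0)
})
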