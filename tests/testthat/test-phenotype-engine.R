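test_that("risk-window offsets include day 0 and the closed upper bound", {
  expect_equal(in_risk_window(as.Date("2021-03-01"), as.Date("2021-03-01")),
               0L)
  expect_equal(in_risk_window(as.Date("2021-03-01"), as.Date("2021-04-12")),
               42L)
  expect_true(is.na(in_risk_window(as.Date("2021-03-01"),
                                   as.Date("2021-04-13"))))
  # diagnosis before vaccination never qualifies
  expect_true(is.na(in_risk_window(as.Date("2021-03-01"),
                                   as.Date("2021-02-20"))))
})

test_that("exposure selection picks the most recent in-window dose", {
  vs <- valueset_for_role(default_valuesets(), "exposure_vaccine")
  cvx <- "http://hl7.org/fhir/sid/cvx"
  dx <- as.Date("2021-06-01")
  imm <- tibble::tibble(
    immunization_id = c("I1", "I2"), patient_id = "P1", system = cvx,
    code = "207", administration_date = dx - c(60, 10))
  sel <- select_exposure(imm, dx, vs)
  expect_equal(sel$immunization_id, "I2")
  expect_equal(sel$exposure_offset_days, 10L)
  # only an out-of-window dose: nothing qualifies
  expect_null(select_exposure(imm[1, ], dx, vs))
  # an in-window non-vaccine code is gated out by the value set
  flu <- tibble::tibble(immunization_id = "I3", patient_id = "P1",
                        system = cvx, code = "140",
                        administration_date = dx - 5)
  expect_null(select_exposure(flu, dx, vs))
  # brute force over random dose sets: minimal non-negative in-window offset
  set.seed(21)
  for (rep in 1:25) {
    k <- sample(1:6, 1)
    doses <- tibble::tibble(
      immunization_id = sprintf("I%02d", 1:k), patient_id = "P1",
      system = cvx, code = sample(c("207", "208", "140"), k, TRUE),
      administration_date = dx - sample(-30:120, k))
    best <- NULL
    for (i in 1:k) {
      if (!doses$code[i] %in% c("207", "208")) next
      off <- as.integer(dx - doses$administration_date[i])
      if (off < 0 || off > 42) next
      if (is.null(best) || off < best$off) best <- list(off = off, id = doses$immunization_id[i])
    }
    sel <- select_exposure(doses, dx, vs)
    if (is.null(best)) {
      expect_null(sel)
    } else {
      expect_equal(sel$exposure_offset_days, best$off)
    }
  }
})

test_that("clean window is a half-open 365-day lookback", {
  vs <- valueset_for_role(default_valuesets(), "target_diagnosis")
  icd <- "http://hl7.org/fhir/sid/icd-10-cm"
  idx <- as.Date("2021-06-01")
  mk <- function(days_before) {
    tibble::tibble(condition_id = "C1", patient_id = "P1",
                   encounter_id = NA, system = icd, code = "I40.9",
                   onset_date = idx - days_before, diagnosis_role = "final")
  }
  expect_false(passes_clean_window(mk(100), "P1", idx, vs))
  expect_true(passes_clean_window(mk(400), "P1", idx, vs))
  expect_true(passes_clean_window(mk(0), "P1", idx, vs))    # same day
  expect_false(passes_clean_window(mk(365), "P1", idx, vs)) # boundary in
  expect_true(passes_clean_window(mk(366), "P1", idx, vs))  # boundary out
  expect_true(passes_clean_window(mk(100)[0, ], "P1", idx, vs)) # no history
})

test_that("detection on a handcrafted bundle flags the right case with provenance", {
  b <- mini_bundle()
  res <- detect(b, default_valuesets())
  expect_equal(res$candidates$patient_id, "P1")
  expect_equal(res$candidates$index_diagnosis_date, as.Date("2021-03-15"))
  expect_equal(res$candidates$exposure_offset_days, 14L)
  expect_equal(res$candidates$qualifying_immunization_id, "I1")
  expect_equal(res$candidates$supporting_evidence_ids, "O1")
  # each ineligible patient is excluded at the stage its structure predicts
  excl <- res$exclusions
  expect_equal(excl$stage[excl$patient_id == "P2"], "clean_window")
  expect_equal(excl$stage[excl$patient_id == "P4"], "vaccine_exposure")
  expect_false("P3" %in% c(res$candidates$patient_id, excl$patient_id))
  expect_true(all(res$attrition$surviving <= res$attrition$entering))
})

test_that("cases with insufficient pre-index history are excluded, not assumed clean", {
  # a condition on an in-study encounter can carry an earlier onset date
  # (carried-over diagnosis); its clean window then reaches before the
  # observation period and cannot be evaluated
  b <- mini_bundle()
  b$conditions$onset_date[1] <- as.Date("2020-10-01")
  b$observations$effective_date[1] <- as.Date("2020-10-02")
  b$immunizations$administration_date[1] <- as.Date("2020-09-25")
  res <- detect(b, default_valuesets())
  excl <- res$exclusions
  expect_false("P1" %in% res$candidates$patient_id)
  expect_equal(excl$reason[excl$patient_id == "P1"],
               "insufficient observation history")
  # config refuses a study period whose start lacks a full clean window
  expect_error(phenotype_config(observation_start = as.Date("2020-06-01")),
               "clean_window_days")
})

test_that("a bundle with no immunizations loses every case at the exposure stage", {
  b <- mini_bundle()
  b$immunizations <- b$immunizations[0, ]
  res <- detect(b, default_valuesets())
  expect_equal(nrow(res$candidates), 0)
  att <- res$attrition
  expect_equal(att$surviving[att$stage == "vaccine_exposure"], 0)
  expect_gt(att$entering[att$stage == "vaccine_exposure"], 0)
})

test_that("admitting-only diagnoses never anchor a case", {
  b <- mini_bundle()
  b$conditions$diagnosis_role[b$conditions$condition_id == "C1"] <- "admitting"
  res <- detect(b, default_valuesets())
  expect_false("P1" %in% res$candidates$patient_id)
  res2 <- detect(b, default_valuesets(),
                 phenotype_config(exclude_admitting_only = FALSE))
  expect_true("P1" %in% res2$candidates$patient_id)
})

test_that("detection agrees with the brute-force oracle on generated cohorts", {
  for (seed in c(101, 202)) {
    cohort <- generate_cohort(cohort_spec(n_patients = 120, n_true_cases = 7,
                                          n_out_of_window_cases = 5,
                                          n_prevalent_cases = 5,
                                          n_outpatient_cases = 5,
                                          n_unvaccinated_cases = 5,
                                          n_duplicate_demographic_cases = 2,
                                          seed = seed))
    vs <- default_valuesets()
    cfg <- phenotype_config()
    got <- detect(cohort$bundle, vs, cfg)$candidates
    want <- oracle_detect(cohort$bundle, vs, cfg)
    expect_equal(got[, names(want)], want, ignore_attr = TRUE)
  }
})

test_that("widening the risk window never removes a candidate", {
  cohort <- generate_cohort(cohort_spec(n_patients = 100, n_true_cases = 6,
                                        n_out_of_window_cases = 6,
                                        seed = 77))
  vs <- default_valuesets()
  narrow <- detect(cohort$bundle, vs,
                   phenotype_config(risk_window_days = c(0, 42)))$candidates
  wide <- detect(cohort$bundle, vs,
                 phenotype_config(risk_window_days = c(0, 120)))$candidates
  expect_true(all(narrow$patient_id %in% wide$patient_id))
  # the out-of-window plants are exactly the candidates gained
  gained <- setdiff(wide$patient_id, narrow$patient_id)
  oow <- cohort$truth$patient_id[cohort$truth$planted_category ==
                                   "out_of_window"]
  expect_setequal(gained, oow)
})

test_that("attrition is monotone and stage counts chain across matching units", {
  cohort <- generate_cohort(cohort_spec(n_patients = 150, seed = 13))
  att <- detect(cohort$bundle, default_valuesets())$attrition
  expect_equal(att$stage, c("study_period", "care_setting",
                            "target_diagnosis", "supporting_evidence",
                            "clean_window", "vaccine_exposure",
                            "one_case_per_patient"))
  expect_true(all(att$surviving <= att$entering))
  same_unit <- which(att$unit[-1] == att$unit[-nrow(att)])
  expect_equal(att$entering[same_unit + 1], att$surviving[same_unit])
})

test_that("a required empty value set is fatal", {
  vs <- default_valuesets()
  expect_error(detect(mini_bundle(), vs[vs$role != "exposure_vaccine", ]),
               "exposure_vaccine")
})
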