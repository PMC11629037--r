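test_that("bundles round-trip through FHIR NDJSON with typed fields intact", {
  cohort <- generate_cohort(cohort_spec(n_patients = 100, seed = 42))
  dir <- withr::local_tempdir()
  write_bundle(cohort$bundle, dir)
  back <- read_bundle(dir)
  expect_equal(nrow(back$rejects), 0)
  srt <- function(tab, key) tab[order(tab[[key]]), ]
  for (spec in list(c("patients", "patient_id"),
                    c("encounters", "encounter_id"),
                    c("conditions", "condition_id"),
                    c("immunizations", "immunization_id"),
                    c("observations", "observation_id"))) {
    expect_equal(srt(back[[spec[1]]], spec[2]),
                 srt(cohort$bundle[[spec[1]]], spec[2]),
                 ignore_attr = TRUE)
  }
  # pass-through resources are preserved verbatim
  expect_setequal(back$passthrough$DiagnosticReport,
                  cohort$bundle$passthrough$DiagnosticReport)
  expect_setequal(back$passthrough$Practitioner,
                  cohort$bundle$passthrough$Practitioner)
  # repeated writes of the same bundle are byte-identical
  dir2 <- withr::local_tempdir()
  write_bundle(cohort$bundle, dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir, f)))
  }
})

test_that("malformed, mistyped and orphaned lines are rejected with reasons", {
  dir <- withr::local_tempdir()
  pat <- function(id) {
    sprintf(paste0('{"resourceType":"Patient","id":"%s",',
                   '"name":[{"text":"a b"}],"gender":"female",',
                   '"birthDate":"1980-01-01"}'), id)
  }
  writeLines(c(pat("P1"), "{not json", pat("P2")),
             file.path(dir, "Patient.ndjson"))
  writeLines(c('{"resourceType":"Observation","id":"X1"}',
               paste0('{"resourceType":"Condition","id":"C9",',
                      '"subject":{"reference":"Patient/NOPE"},',
                      '"code":{"coding":[{"system":"s","code":"I40"}]},',
                      '"onsetDateTime":"2021-01-01"}')),
             file.path(dir, "Condition.ndjson"))
  b <- read_bundle(dir)
  expect_equal(nrow(b$patients), 2)
  expect_equal(nrow(b$conditions), 0)
  expect_equal(sum(b$rejects$file == "Patient"), 1)
  expect_match(b$rejects$reason[b$rejects$file == "Patient"],
               "malformed JSON")
  expect_true(any(grepl("unexpected resourceType", b$rejects$reason)))
  expect_true(any(grepl("unknown patient_id: NOPE", b$rejects$reason)))
  # accepted + rejected accounts for every line
  expect_equal(nrow(b$patients) + sum(b$rejects$file == "Patient"), 3)
  expect_equal(nrow(b$conditions) + sum(b$rejects$file == "Condition"), 2)
})

test_that("an empty Patient file yields an empty bundle; a missing one is fatal", {
  dir <- withr::local_tempdir()
  file.create(file.path(dir, "Patient.ndjson"))
  b <- read_bundle(dir)
  expect_equal(nrow(b$patients), 0)
  expect_equal(nrow(b$encounters) + nrow(b$conditions) +
                 nrow(b$immunizations) + nrow(b$observations), 0)
  dir2 <- withr::local_tempdir()
  writeLines("{}", file.path(dir2, "Observation.ndjson"))
  expect_error(read_bundle(dir2), "Patient")
})

test_that("bundle invariants are enforced", {
  b <- mini_bundle()
  bad <- b
  bad$conditions$patient_id[1] <- "GHOST"
  expect_error(validate_bundle(bad), "unknown patient_id")
  bad2 <- b
  bad2$encounters$end_date[1] <- bad2$encounters$start_date[1] - 1
  expect_error(validate_bundle(bad2), "end_date")
  bad3 <- b
  bad3$patients$sex[1] <- "m"
  expect_error(validate_bundle(bad3), "invalid sex")
})

test_that("shipped value sets load with one set per role", {
  vs <- default_valuesets()
  expect_setequal(unique(vs$role),
                  c("target_diagnosis", "supporting_evidence",
                    "exposure_vaccine"))
  expect_equal(length(unique(vs$name)), 3)
})

test_that("duplicate entries and unknown roles are fatal, naming the offender", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "vs.csv")
  base <- utils::read.csv(system.file("extdata", "valuesets.csv",
                                      package = "phenoval"))
  dup <- rbind(base, data.frame(name = "myopericarditis_dx",
                                role = "target_diagnosis",
                                system = "http://hl7.org/fhir/sid/icd-10-cm",
                                code = "I41", prefix = "FALSE",
                                description = "dup"))
  utils::write.csv(dup, f, row.names = FALSE)
  expect_error(load_valuesets(f), "I41")
  bad <- base
  bad$role[1] <- "diagnosis"
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(load_valuesets(f), "unknown value-set role")
  # a config missing a required role is rejected
  utils::write.csv(base[base$role != "exposure_vaccine", ], f,
                   row.names = FALSE)
  expect_error(load_valuesets(f), "exposure_vaccine")
})

test_that("value-set membership agrees with a linear-scan oracle", {
  vs <- default_valuesets()
  vs <- vs[vs$role == "target_diagnosis", ]
  set.seed(7)
  systems <- sample(c("http://hl7.org/fhir/sid/icd-10-cm", "http://loinc.org",
                      " http://hl7.org/fhir/sid/icd-10-cm "), 200, TRUE)
  codes <- sample(c("I40", "I40.0", "I40.83", "i40.0", "I41", "I41.1",
                    "I51.4", "I51.40", "I30", "I32", "I325", "J40",
                    " I40.9 "), 200, TRUE)
  got <- coding_in_valueset(systems, codes, vs)
  want <- mapply(oracle_member, systems, codes, MoreArgs = list(vs = vs))
  expect_equal(unname(got), unname(want))
  # spot checks: exact is case-sensitive, prefix covers the family
  expect_false(coding_in_valueset("http://hl7.org/fhir/sid/icd-10-cm",
                                  "i41", vs))
  expect_true(coding_in_valueset("http://hl7.org/fhir/sid/icd-10-cm",
                                 "I30.9", vs))
  expect_false(coding_in_valueset("http://loinc.org", "I41", vs))
})

test_that("value sets also load from YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    list(name = "dx", role = "target_diagnosis", description = "d",
         entries = list(list(system = "s", code = "I40", prefix = TRUE))),
    list(name = "ev", role = "supporting_evidence",
         entries = list(list(system = "l", code = "6598-7"))),
    list(name = "vx", role = "exposure_vaccine",
         entries = list(list(system = "c", code = "207")))), f)
  vs <- load_valuesets(f)
  expect_equal(nrow(vs), 3)
  expect_true(vs$prefix[vs$name == "dx"])
  expect_false(any(vs$prefix[vs$name != "dx"]))
})
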