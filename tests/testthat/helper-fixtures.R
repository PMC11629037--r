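# Small handcrafted bundle: one clean detectable case (P1), one prevalent
# patient (P2), one outpatient-only patient (P3), one unvaccinated (P4).
mini_bundle <- function() {
  icd <- "http://hl7.org/fhir/sid/icd-10-cm"
  loinc <- "http://loinc.org"
  cvx <- "http://hl7.org/fhir/sid/cvx"
  d <- function(x) as.Date(x)
  patients <- tibble::tibble(
    patient_id = c("P1", "P2", "P3", "P4"),
    name = c("Ada Park", "Ben Cole", "Cam Diaz", "Dee Fox"),
    name_key = normalize_name(name),
    birth_date = d(c("1980-01-01", "1975-05-05", "1990-09-09", "1960-03-03")),
    sex = c("female", "male", "female", "male"),
    race = "white", ethnicity = "non_hispanic")
  encounters <- tibble::tibble(
    encounter_id = c("E1", "E2", "E3", "E4"),
    patient_id = c("P1", "P2", "P3", "P4"),
    care_setting = c("inpatient", "inpatient", "outpatient", "inpatient"),
    start_date = d(c("2021-03-15", "2021-06-01", "2021-07-01", "2021-08-01")),
    end_date = d(c("2021-03-18", "2021-06-03", "2021-07-01", "2021-08-04")))
  conditions <- tibble::tibble(
    condition_id = c("C1", "C2", "C2p", "C3", "C4"),
    patient_id = c("P1", "P2", "P2", "P3", "P4"),
    encounter_id = c("E1", "E2", NA, "E3", "E4"),
    system = icd,
    code = c("I40.9", "I30.0", "I30.1", "I40.1", "I51.4"),
    onset_date = d(c("2021-03-15", "2021-06-01", "2021-02-01", "2021-07-01",
                     "2021-08-01")),
    diagnosis_role = "final")
  immunizations <- tibble::tibble(
    immunization_id = c("I1", "I2", "I3"),
    patient_id = c("P1", "P2", "P3"),
    system = cvx, code = c("207", "208", "207"),
    administration_date = d(c("2021-03-01", "2021-05-20", "2021-06-20")))
  observations <- tibble::tibble(
    observation_id = c("O1", "O2", "O3", "O4"),
    patient_id = c("P1", "P2", "P3", "P4"),
    system = loinc, code = "6598-7",
    effective_date = d(c("2021-03-16", "2021-06-01", "2021-07-01",
                         "2021-08-02")),
    value = c(4.2, 1.1, 0.3, 2.5))
  new_bundle(patients = patients, encounters = encounters,
             conditions = conditions, immunizations = immunizations,
             observations = observations)
}
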