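#' @title End-to-end pipeline
#' @description Chains detection, retrieval, simulated adjudication and the
#'   validation statistics over one bundle, mirroring the workflow of an
#'   exchange-based active-surveillance validation study.
#' @name pipeline
NULL

#' Run the full surveillance pipeline on a bundle
#'
#' @param bundle an `ehr_bundle`.
#' @param truth truth-label tibble driving the simulated reviewers (see
#'   [generate_cohort()]).
#' @param valuesets value-set tibble (default: shipped sets).
#' @param config a [phenotype_config()].
#' @param sensitivity_to_truth,agreement_rate reviewer-simulation
#'   parameters.
#' @param seed seed for the simulated reviews and tie-breaks.
#' @return List with `candidates`, `attrition` (detection + retrieval
#'   stages), `exclusions`, `payloads`, `reviews`, `adjudications` and
#'   `report`.
#' @export
run_pipeline <- function(bundle, truth, valuesets = default_valuesets(),
                         config = phenotype_config(),
                         sensitivity_to_truth = 0.9, agreement_rate = 0.8,
                         seed = 1L) {
  det <- detect(bundle, valuesets, config)
  ret <- retrieve_all(det$candidates, bundle,
                      c(config$study_start, config$study_end))
  reviews <- simulate_reviews(truth, ret$payloads,
                              sensitivity_to_truth = sensitivity_to_truth,
                              agreement_rate = agreement_rate, seed = seed)
  adjudications <- if (nrow(reviews)) {
    adjudicate_all(reviews,
                   make_truth_tiebreaker(truth, sensitivity_to_truth,
                                         seed = seed + 1L))
  } else {
    tibble(case_id = character(), reviewer1 = character(),
           reviewer2 = character(), tiebreak = character(),
           final = character(), is_true_positive = logical(),
           is_insufficient = logical())
  }
  attrition <- bind_rows(det$attrition, ret$attrition)
  report <- build_report(adjudications, attrition = attrition,
                         reviews = reviews)
  list(candidates = det$candidates, attrition = attrition,
       exclusions = list(detection = det$exclusions,
                         retrieval = ret$exclusions),
       payloads = ret$payloads, reviews = reviews,
       adjudications = adjudications, report = report)
}

#' Write pipeline artifacts to a directory
#'
#' Emits `candidates.csv`, `attrition.json`, `reviews.csv`,
#' `adjudications.csv`, `report.json` and `report.md`.
#'
#' @param results list returned by [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the files written.
#' @export
write_pipeline_outputs <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(candidates = file.path(dir, "candidates.csv"),
             attrition = file.path(dir, "attrition.json"),
             reviews = file.path(dir, "reviews.csv"),
             adjudications = file.path(dir, "adjudications.csv"),
             report_json = file.path(dir, "report.json"),
             report_md = file.path(dir, "report.md"))
  write.csv(results$candidates, paths[["candidates"]], row.names = FALSE)
  jsonlite::write_json(lapply(seq_len(nrow(results$attrition)), function(i) {
    as.list(results$attrition[i, ])
  }), paths[["attrition"]], auto_unbox = TRUE, pretty = TRUE)
  write.csv(results$reviews, paths[["reviews"]], row.names = FALSE)
  write.csv(results$adjudications, paths[["adjudications"]],
            row.names = FALSE)
  jsonlite::write_json(report_to_list(results$report), paths[["report_json"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  md <- utils::capture.output(print(results$report))
  writeLines(c("# Validation report", "", "```", md, "```"),
             paths[["report_md"]])
  invisible(paths)
}
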