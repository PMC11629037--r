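#' @title Two-reviewer adjudication bookkeeping
#' @description Each retrieved case is reviewed independently by two
#'   clinicians using the conventional diagnostic-certainty categories
#'   (definite, probable, possible, doubtful) plus an insufficient-evidence
#'   flag for cases whose documentation cannot support a determination.
#'   Disagreements go to a third reviewer whose label is final. A simulator
#'   driven by latent truth labels stands in for human reviewers in tests
#'   and synthetic studies.
#' @name adjudication
NULL

CLASSIFICATIONS <- c("definite", "probable", "possible", "doubtful",
                     "insufficient_evidence")
TRUE_POSITIVE_CLASSES <- c("definite", "probable")

#' Resolve one case's two reviews into a final adjudication
#'
#' When the two reviewers agree, their shared label is final and the
#' tie-break provider is never consulted; on disagreement it is consulted
#' exactly once and its label is final.
#'
#' @param review1,review2 lists (or one-row data frames) with `case_id` and
#'   `classification`; both must refer to the same case.
#' @param tiebreak_provider `function(case_id) -> classification`, the third
#'   reviewer.
#' @return One-row tibble: `case_id`, `reviewer1`, `reviewer2`, `tiebreak`
#'   (NA when not consulted), `final`, `is_true_positive` (final is definite
#'   or probable), `is_insufficient`.
#' @export
resolve <- function(review1, review2, tiebreak_provider = NULL) {
  r1 <- as.list(review1); r2 <- as.list(review2)
  if (!identical(r1$case_id, r2$case_id)) {
    abort("reviews refer to different cases")
  }
  for (lab in c(r1$classification, r2$classification)) {
    if (!lab %in% CLASSIFICATIONS) {
      abort(sprintf("unknown classification: %s", lab))
    }
  }
  if (identical(r1$classification, r2$classification)) {
    tiebreak <- NA_character_
    final <- r1$classification
  } else {
    if (is.null(tiebreak_provider)) {
      abort("reviewers disagree and no tiebreak_provider given")
    }
    tiebreak <- tiebreak_provider(r1$case_id)
    if (!is.character(tiebreak) || length(tiebreak) != 1 ||
        !tiebreak %in% CLASSIFICATIONS) {
      abort("tiebreak_provider returned a label outside the classification set")
    }
    final <- tiebreak
  }
  tibble(case_id = r1$case_id, reviewer1 = r1$classification,
         reviewer2 = r2$classification, tiebreak = tiebreak, final = final,
         is_true_positive = final %in% TRUE_POSITIVE_CLASSES,
         is_insufficient = final == "insufficient_evidence")
}

#' Adjudicate all cases from a long reviews table
#'
#' @param reviews tibble with `case_id`, `reviewer` (`"reviewer1"` /
#'   `"reviewer2"`), `classification` — e.g. from [simulate_reviews()].
#' @param tiebreak_provider `function(case_id) -> classification`; see
#'   [make_truth_tiebreaker()] for a simulated third reviewer.
#' @return Tibble of adjudication records (one row per case; see
#'   [resolve()]).
#' @export
adjudicate_all <- function(reviews, tiebreak_provider = NULL) {
  wide <- tidyr::pivot_wider(reviews, id_cols = "case_id",
                             names_from = "reviewer",
                             values_from = "classification")
  stopifnot(all(c("reviewer1", "reviewer2") %in% names(wide)))
  bind_rows(lapply(seq_len(nrow(wide)), function(i) {
    resolve(list(case_id = wide$case_id[[i]],
                 classification = wide$reviewer1[[i]]),
            list(case_id = wide$case_id[[i]],
                 classification = wide$reviewer2[[i]]),
            tiebreak_provider)
  }))
}

draw_classification <- function(is_true, sensitivity) {
  n <- length(is_true)
  toward_truth <- runif(n) < sensitivity
  positive_call <- xor(!is_true, toward_truth)
  pick_hi <- runif(n) < 0.5
  ifelse(positive_call,
         ifelse(pick_hi, "definite", "probable"),
         ifelse(pick_hi, "possible", "doubtful"))
}

#' Simulate the two primary reviewers from latent truth labels
#'
#' Cases with `evidence_complete = FALSE` are labeled
#' `insufficient_evidence` by both reviewers. Otherwise reviewer 1 calls the
#' case positive (definite or probable, split evenly) with probability
#' `sensitivity_to_truth` when the latent label is a true adverse event, and
#' negative (possible or doubtful) otherwise; reviewer 2 copies reviewer 1
#' with probability `agreement_rate`, else draws independently under the
#' same scheme. A non-NA `fixed_class` in the truth table pins both
#' reviewers to that label (used by deterministic fixtures).
#'
#' @param truth truth tibble (see [generate_cohort()]).
#' @param case_ids character vector of case ids to review, or a list of
#'   `case_payload` objects.
#' @param sensitivity_to_truth,agreement_rate probabilities in \[0, 1\].
#' @param seed integer seed; reviews are deterministic given the seed.
#' @return Long tibble `case_id`, `reviewer`, `classification`.
#' @export
simulate_reviews <- function(truth, case_ids, sensitivity_to_truth = 0.9,
                             agreement_rate = 0.8, seed = 1L) {
  stopifnot(sensitivity_to_truth >= 0, sensitivity_to_truth <= 1,
            agreement_rate >= 0, agreement_rate <= 1)
  if (is.list(case_ids) && !is.character(case_ids)) {
    case_ids <- vapply(case_ids, function(p) p$case_id, character(1))
  }
  tl <- truth[match(case_ids, truth$patient_id), ]
  if (anyNA(tl$patient_id)) abort("case id missing from truth labels")
  with_cohort_seed(seed, {
    n <- length(case_ids)
    r1 <- draw_classification(tl$is_true_ae, sensitivity_to_truth)
    copy <- runif(n) < agreement_rate
    r2 <- ifelse(copy, r1, draw_classification(tl$is_true_ae,
                                               sensitivity_to_truth))
    insufficient <- !tl$evidence_complete
    r1[insufficient] <- "insufficient_evidence"
    r2[insufficient] <- "insufficient_evidence"
    pinned <- !is.na(tl$fixed_class) & !insufficient
    r1[pinned] <- tl$fixed_class[pinned]
    r2[pinned] <- tl$fixed_class[pinned]
    tibble(case_id = rep(case_ids, 2),
           reviewer = rep(c("reviewer1", "reviewer2"), each = n),
           classification = c(r1, r2))
  })
}

#' Simulated third reviewer for tie-breaking
#'
#' Pre-draws one independent classification per truth-labeled case under the
#' same scheme as [simulate_reviews()]; the returned function looks the
#' label up by case id, so tie-break outcomes are deterministic given the
#' seed and independent of the first two reviews.
#'
#' @inheritParams simulate_reviews
#' @return `function(case_id) -> classification`.
#' @export
make_truth_tiebreaker <- function(truth, sensitivity_to_truth = 0.9,
                                  seed = 2L) {
  labels <- with_cohort_seed(seed, {
    lab <- draw_classification(truth$is_true_ae, sensitivity_to_truth)
    lab[!truth$evidence_complete] <- "insufficient_evidence"
    pinned <- !is.na(truth$fixed_class) & truth$evidence_complete
    lab[pinned] <- truth$fixed_class[pinned]
    setNames(lab, truth$patient_id)
  })
  function(case_id) {
    if (!case_id %in% names(labels)) {
      abort(sprintf("no truth label for case %s", case_id))
    }
    unname(labels[[case_id]])
  }
}
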