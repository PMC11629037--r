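#' @title Validation statistics
#' @description The statistical layer of a chart-review validation study:
#'   positive predictive value under the primary convention (insufficient-
#'   evidence cases excluded from the denominator) and the alternate
#'   convention (counted as false positives), Agresti-Coull binomial
#'   confidence intervals, Cohen kappa interrater agreement, and the pooled
#'   two-sample proportion z test used to compare PPVs across sites.
#' @name validation_stats
NULL

#' Classification counts for a validation sample
#'
#' @param definite,probable,possible,doubtful,insufficient non-negative
#'   integer counts of final case classifications.
#' @return A `classification_counts` list with the raw counts and the
#'   derived quantities `tp` (definite + probable), `fp` (possible +
#'   doubtful), `n_sufficient` (tp + fp) and `n_total`
#'   (n_sufficient + insufficient).
#' @export
classification_counts <- function(definite = 0, probable = 0, possible = 0,
                                  doubtful = 0, insufficient = 0) {
  x <- c(definite = definite, probable = probable, possible = possible,
         doubtful = doubtful, insufficient = insufficient)
  if (any(x < 0) || any(x != round(x))) {
    abort("counts must be non-negative integers")
  }
  x <- as.integer(x)
  structure(list(definite = x[[1]], probable = x[[2]], possible = x[[3]],
                 doubtful = x[[4]], insufficient = x[[5]],
                 tp = x[[1]] + x[[2]], fp = x[[3]] + x[[4]],
                 n_sufficient = sum(x[1:4]), n_total = sum(x)),
            class = "classification_counts")
}

#' Tally classification counts from adjudication records
#' @param adjudications tibble from [adjudicate_all()].
#' @return A [classification_counts()] object.
#' @export
count_classifications <- function(adjudications) {
  f <- factor(adjudications$final, levels = CLASSIFICATIONS)
  tab <- table(f)
  classification_counts(definite = tab[["definite"]],
                        probable = tab[["probable"]],
                        possible = tab[["possible"]],
                        doubtful = tab[["doubtful"]],
                        insufficient = tab[["insufficient_evidence"]])
}

#' Agresti-Coull confidence interval for a binomial proportion
#'
#' With `z` the standard-normal quantile at `(1 + conf_level) / 2`, the
#' adjusted trial count is `n~ = n + z^2`, the adjusted proportion
#' `p~ = (x + z^2/2) / n~`, and the interval
#' `p~ +/- z * sqrt(p~ (1 - p~) / n~)`, clamped to \[0, 1\].
#'
#' @param x successes (0 <= x <= n).
#' @param n trials (> 0).
#' @param conf_level confidence level (default 0.95).
#' @return Named numeric `c(low, high)`.
#' @export
agresti_coull_ci <- function(x, n, conf_level = 0.95) {
  if (any(n <= 0)) abort("n must be positive")
  if (any(x < 0 | x > n)) abort("x must lie in [0, n]")
  z <- qnorm((1 + conf_level) / 2)
  n_adj <- n + z^2
  p_adj <- (x + z^2 / 2) / n_adj
  half <- z * sqrt(p_adj * (1 - p_adj) / n_adj)
  c(low = pmax(0, p_adj - half), high = pmin(1, p_adj + half))
}

new_proportion_estimate <- function(x, n, conf_level, method) {
  ci <- agresti_coull_ci(x, n, conf_level)
  structure(list(x = x, n = n, point = x / n, ci_low = unname(ci[["low"]]),
                 ci_high = unname(ci[["high"]]), conf_level = conf_level,
                 method = method),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%d%% CI %.1f%%-%.1f%%, %s)\n", x$x, x$n,
              100 * x$point, round(100 * x$conf_level), 100 * x$ci_low,
              100 * x$ci_high, x$method))
  invisible(x)
}

#' Positive predictive value of the algorithm
#'
#' Primary convention (`include_insufficient = FALSE`): true positives
#' (definite + probable) over all adjudicated cases with sufficient
#' evidence. Alternate convention: insufficient-evidence cases counted as
#' false positives, i.e. the denominator is all cases selected by the
#' algorithm and reviewed.
#'
#' @param counts a [classification_counts()] object.
#' @param include_insufficient use the alternate denominator (default
#'   FALSE).
#' @param conf_level confidence level for the Agresti-Coull interval.
#' @return A `proportion_estimate` (`x`, `n`, `point`, `ci_low`, `ci_high`).
#' @export
ppv <- function(counts, include_insufficient = FALSE, conf_level = 0.95) {
  stopifnot(inherits(counts, "classification_counts"))
  n <- if (include_insufficient) counts$n_total else counts$n_sufficient
  if (n == 0) abort("PPV undefined: zero denominator")
  new_proportion_estimate(counts$tp, n, conf_level, "agresti-coull")
}

#' Cohen kappa between two raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement
#' proportion and `p_e` the chance agreement from the raters' marginal
#' label distributions.
#'
#' @param labels_a,labels_b equal-length label vectors over a shared finite
#'   category set.
#' @return Kappa in \[-1, 1\]. Errors (rather than silently returning 0)
#'   when chance agreement is 1, i.e. both raters are constant with
#'   identical margins.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || !length(labels_a)) {
    abort("label vectors must be non-empty and of equal length")
  }
  levels <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = levels)
  b <- factor(labels_b, levels = levels)
  p_o <- mean(a == b)
  p_e <- sum(prop.table(table(a)) * prop.table(table(b)))
  if (isTRUE(all.equal(p_e, 1))) {
    abort("kappa undefined: chance agreement is 1 (constant identical margins)")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Pooled two-sample proportion z test
#'
#' `z = (x1/n1 - x2/n2) / sqrt(p(1-p)(1/n1 + 1/n2))` with
#' `p = (x1 + x2) / (n1 + n2)` the pooled proportion; the p-value is
#' two-sided standard normal. No continuity correction.
#'
#' @param x1,n1,x2,n2 successes and trials of the two samples.
#' @return List with `z`, `p_value`, `p1`, `p2`, `pooled`.
#' @export
two_sample_proportion_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0 || x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) {
    abort("invalid counts")
  }
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    abort("degenerate pooled proportion: variance is zero")
  }
  z <- (x1 / n1 - x2 / n2) /
    sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * pnorm(-abs(z)), p1 = x1 / n1, p2 = x2 / n2,
       pooled = pooled)
}

#' Build the validation report
#'
#' Assembles the study's summary table: final classification counts, true
#' and false positives, PPV under both conventions with Agresti-Coull
#' intervals, the insufficient-evidence share, interrater kappa (when the
#' primary reviews are supplied), and the attrition table.
#'
#' @param adjudications tibble from [adjudicate_all()] (may have zero rows).
#' @param attrition optional attrition tibble (detection and/or retrieval
#'   stages).
#' @param reviews optional long reviews tibble; kappa is computed between
#'   reviewer 1 and reviewer 2 over all reviewed cases, with
#'   insufficient-evidence treated as its own category.
#' @param conf_level confidence level for intervals.
#' @return A `validation_report` list; percentages are stored at full
#'   precision and rounded to one decimal only for printing.
#' @export
build_report <- function(adjudications, attrition = NULL, reviews = NULL,
                         conf_level = 0.95) {
  counts <- if (nrow(adjudications)) count_classifications(adjudications)
  else classification_counts()
  safe_ppv <- function(include) {
    tryCatch(ppv(counts, include_insufficient = include, conf_level),
             error = function(e) NULL)
  }
  kappa <- NULL
  if (!is.null(reviews) && nrow(reviews)) {
    wide <- tidyr::pivot_wider(reviews, id_cols = "case_id",
                               names_from = "reviewer",
                               values_from = "classification")
    kappa <- tryCatch(cohen_kappa(wide$reviewer1, wide$reviewer2),
                      error = function(e) NULL)
  }
  structure(list(
    counts = counts,
    ppv = safe_ppv(FALSE),
    ppv_alternate = safe_ppv(TRUE),
    insufficient_share = if (counts$n_total > 0) {
      counts$insufficient / counts$n_total
    } else NA_real_,
    kappa = kappa, attrition = attrition, conf_level = conf_level),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  c_ <- x$counts
  cat("Validation sample results\n")
  cat(sprintf("  Definite, n                          %d\n", c_$definite))
  cat(sprintf("  Probable, n                          %d\n", c_$probable))
  cat(sprintf("  Possible, n                          %d\n", c_$possible))
  cat(sprintf("  Doubtful, n                          %d\n", c_$doubtful))
  cat(sprintf("  True positives (definite+probable)   %d\n", c_$tp))
  cat(sprintf("  False positives (possible+doubtful)  %d\n", c_$fp))
  cat(sprintf("  Cases with sufficient evidence, n    %d\n", c_$n_sufficient))
  fmt_ppv <- function(p) {
    if (is.null(p)) return("undefined")
    sprintf("%.1f (%.1f-%.1f)", 100 * p$point, 100 * p$ci_low,
            100 * p$ci_high)
  }
  cat(sprintf("  PPV, %% (95%% CI)                      %s\n", fmt_ppv(x$ppv)))
  cat(sprintf("  Insufficient evidence, n             %d\n", c_$insufficient))
  cat(sprintf("  Total cases, n                       %d\n", c_$n_total))
  cat(sprintf("  Insufficient evidence, %%             %s\n",
              if (is.na(x$insufficient_share)) "undefined"
              else sprintf("%.1f", 100 * x$insufficient_share)))
  cat(sprintf("  PPV alternate, %% (95%% CI)            %s\n",
              fmt_ppv(x$ppv_alternate)))
  if (!is.null(x$kappa)) {
    cat(sprintf("  Interrater Cohen kappa               %.3f\n", x$kappa))
  }
  invisible(x)
}

#' Serialize a validation report to JSON-ready values
#' @param report a `validation_report`.
#' @return A plain list suitable for `jsonlite::write_json()`.
#' @export
report_to_list <- function(report) {
  c_ <- report$counts
  pe <- function(p) if (is.null(p)) NULL else
    list(x = p$x, n = p$n, point = p$point, ci_low = p$ci_low,
         ci_high = p$ci_high)
  list(counts = list(definite = c_$definite, probable = c_$probable,
                     possible = c_$possible, doubtful = c_$doubtful,
                     insufficient = c_$insufficient, tp = c_$tp, fp = c_$fp,
                     n_sufficient = c_$n_sufficient, n_total = c_$n_total),
       ppv = pe(report$ppv), ppv_alternate = pe(report$ppv_alternate),
       insufficient_share = report$insufficient_share,
       kappa = report$kappa,
       attrition = if (!is.null(report$attrition)) {
         lapply(seq_len(nrow(report$attrition)), function(i) {
           as.list(report$attrition[i, ])
         })
       })
}
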