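# Evaluation battery: classification-quality metrics over expert-labelled
# reports, chance-corrected inter-rater agreement, and Likert scoring of a
# technology-acceptance questionnaire.

#' Classification metrics over expert-labelled reports
#'
#' Computes the report-quality criteria used to evaluate the decision
#' support against expert review of generated reports:
#' \describe{
#'   \item{error_rate}{`n_mistakes / n_reports`, the average
#'     classification error.}
#'   \item{accuracy}{`1 - error_rate`.}
#'   \item{precision}{`(n_reports - n_mistakes) / n_reports` — the
#'     all-terms-minus-mistakes form used when every generated report is
#'     a positive prediction.}
#'   \item{recall}{`tp / (tp + fn)`, requiring true-positive and
#'     false-negative counts.}
#'   \item{f_measure}{`2 * precision * recall / (precision + recall)`.}
#' }
#' Quantities whose denominator is zero (e.g. recall with `tp + fn = 0`,
#' or when `tp`/`fn` are not supplied) are reported as `NA` (undefined)
#' rather than invented.
#'
#' @param n_reports Number of labelled reports; must be positive.
#' @param n_mistakes Reports judged incorrect; at most `n_reports`.
#' @param tp,fn Optional true-positive and false-negative counts for
#'   recall (and hence the F-measure).
#' @return An object of class `lab_metrics_report` with the five fields
#'   above (unrounded; the print method shows 2 decimals).
#' @export
#' @examples
#' classification_metrics(1000, 7, tp = 993, fn = 7)
classification_metrics <- function(n_reports, n_mistakes, tp = NULL,
                                   fn = NULL) {
  if (!is_scalar_number(n_reports) || n_reports <= 0) {
    stop_labdss("n_reports must be a positive count", "labdss_domain_error")
  }
  if (!is_scalar_number(n_mistakes) || n_mistakes < 0) {
    stop_labdss("n_mistakes must be a non-negative count",
                "labdss_domain_error")
  }
  if (n_mistakes > n_reports) {
    stop_labdss("n_mistakes cannot exceed n_reports", "labdss_domain_error")
  }
  error_rate <- n_mistakes / n_reports
  precision <- (n_reports - n_mistakes) / n_reports
  recall <- if (!is.null(tp) && !is.null(fn)) {
    if (tp < 0 || fn < 0) {
      stop_labdss("tp and fn must be non-negative", "labdss_domain_error")
    }
    if (tp + fn > 0) tp / (tp + fn) else NA_real_
  } else {
    NA_real_
  }
  structure(list(
    n_reports = n_reports,
    n_mistakes = n_mistakes,
    error_rate = error_rate,
    accuracy = 1 - error_rate,
    precision = precision,
    recall = recall,
    f_measure = f_measure(precision, recall)
  ), class = "lab_metrics_report")
}

#' F-measure from precision and recall
#'
#' `2 * precision * recall / (precision + recall)`; `NA` when either
#' input is `NA` or both are zero (undefined harmonic mean).
#'
#' @param precision,recall Proportions in `[0, 1]`.
#' @return The F-measure, or `NA`.
#' @export
#' @examples
#' f_measure(0.5, 1.0)  # 2/3
f_measure <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' @export
print.lab_metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f", v)
  cat(sprintf("Reports analysed: %d, mistakes: %d (%.1f%%)\n",
              x$n_reports, x$n_mistakes, 100 * x$error_rate))
  cat(sprintf("Accuracy: %s  Precision: %s  Recall: %s  F-measure: %s\n",
              fmt(x$accuracy), fmt(x$precision), fmt(x$recall),
              fmt(x$f_measure)))
  invisible(x)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)`, where `po`
#' is the observed fraction of identical labels and `pe` the agreement
#' expected from the raters' marginal label frequencies. When `pe = 1`
#' (both raters constant on the same label), kappa is defined as 1 if
#' agreement is perfect and `NA` (undefined) otherwise.
#'
#' @param labels_a,labels_b Equal-length label vectors (character or
#'   factor) from the two raters.
#' @return An object of class `lab_kappa_result` with
#'   `observed_agreement`, `expected_agreement` and `kappa`.
#' @export
#' @examples
#' cohens_kappa(c("CORRECT", "CORRECT", "INCORRECT"),
#'              c("CORRECT", "INCORRECT", "INCORRECT"))
cohens_kappa <- function(labels_a, labels_b) {
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  if (length(labels_a) != length(labels_b)) {
    stop_labdss("label vectors must have equal length", "labdss_domain_error")
  }
  n <- length(labels_a)
  if (n < 1L) {
    stop_labdss("at least one labelled item is required",
                "labdss_domain_error")
  }
  po <- mean(labels_a == labels_b)
  categories <- union(labels_a, labels_b)
  pe <- sum(vapply(categories, function(k) {
    mean(labels_a == k) * mean(labels_b == k)
  }, numeric(1)))
  kappa <- if (pe < 1) {
    (po - pe) / (1 - pe)
  } else if (po == 1) {
    1
  } else {
    NA_real_
  }
  structure(list(
    observed_agreement = po,
    expected_agreement = pe,
    kappa = kappa
  ), class = "lab_kappa_result")
}

#' @export
print.lab_kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %s (po = %.4f, pe = %.4f)\n",
              if (is.na(x$kappa)) "undefined" else sprintf("%.4f", x$kappa),
              x$observed_agreement, x$expected_agreement))
  invisible(x)
}

#' Default acceptance-questionnaire item map
#'
#' The technology-acceptance instrument measures four criteria on 1-7
#' Likert items: behavioral intention to use (BI, 2 items), intrinsic
#' motivation (IM, 3), perceived ease of use (PEOU, 3) and perceived
#' usefulness (PU, 3).
#'
#' @return A data frame with columns `item` and `criterion`.
#' @export
acceptance_item_map <- function() {
  data.frame(
    item = c("BI1", "BI2",
             "IM1", "IM2", "IM3",
             "PEOU1", "PEOU2", "PEOU3",
             "PU1", "PU2", "PU3"),
    criterion = c("BI", "BI", rep("IM", 3), rep("PEOU", 3), rep("PU", 3)),
    stringsAsFactors = FALSE
  )
}

#' Score a technology-acceptance survey
#'
#' Aggregates a respondent-by-item table of 1-7 Likert responses into
#' per-item means/medians/max/min and per-criterion means (the mean of a
#' criterion's item means). The item map must assign exactly 2 items to
#' BI and 3 each to IM, PEOU and PU. When an `age` vector is supplied,
#' the same aggregation is recomputed for the over-60 and under-60
#' subgroups.
#'
#' @param responses Data frame of integer Likert values in `[1, 7]`; one
#'   row per respondent, one column per item named as in `item_map`.
#' @param item_map Data frame with columns `item`, `criterion`; defaults
#'   to [acceptance_item_map()].
#' @param age Optional numeric vector of respondent ages (one per row)
#'   for the over/under-60 subgroup split.
#' @return An object of class `lab_acceptance_scores` with `items` (per
#'   item: criterion, mean, median, max, min), `criteria` (per-criterion
#'   means) and optional `subgroups`.
#' @export
#' @examples
#' set.seed(1)
#' resp <- generate_survey(20, stats::setNames(rep(6, 11),
#'                                             acceptance_item_map()$item),
#'                         seed = 1)
#' score_acceptance(resp)
score_acceptance <- function(responses, item_map = acceptance_item_map(),
                             age = NULL) {
  required <- c(BI = 2L, IM = 3L, PEOU = 3L, PU = 3L)
  counts <- table(item_map$criterion)
  for (crit in names(required)) {
    if (is.na(counts[crit]) || counts[crit] != required[[crit]]) {
      stop_labdss(sprintf(
        "item map must assign %d item(s) to %s", required[[crit]], crit
      ), "labdss_domain_error")
    }
  }
  missing_items <- setdiff(item_map$item, names(responses))
  if (length(missing_items) > 0L) {
    stop_labdss(sprintf("responses missing item column(s): %s",
                        paste(missing_items, collapse = ", ")),
                "labdss_domain_error")
  }
  if (nrow(responses) == 0L) {
    stop_labdss("at least one respondent is required", "labdss_domain_error")
  }
  for (item in item_map$item) {
    v <- responses[[item]]
    bad <- which(!is.finite(v) | v < 1 | v > 7 | v != round(v))
    if (length(bad) > 0L) {
      stop_labdss(sprintf(
        "respondent %d, item '%s': Likert value must be an integer in [1, 7] (got %s)",
        bad[1], item, format(v[bad[1]])
      ), "labdss_domain_error")
    }
  }
  if (!is.null(age) && length(age) != nrow(responses)) {
    stop_labdss("age must have one value per respondent",
                "labdss_domain_error")
  }

  aggregate_rows <- function(rows) {
    items <- data.frame(
      item = item_map$item,
      criterion = item_map$criterion,
      mean = vapply(item_map$item, function(i) mean(rows[[i]]), numeric(1)),
      median = vapply(item_map$item, function(i) median(rows[[i]]),
                      numeric(1)),
      max = vapply(item_map$item, function(i) max(rows[[i]]), numeric(1)),
      min = vapply(item_map$item, function(i) min(rows[[i]]), numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
    criteria <- data.frame(
      criterion = names(required),
      mean = vapply(names(required), function(crit) {
        mean(items$mean[items$criterion == crit])
      }, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
    list(items = items, criteria = criteria, n = nrow(rows))
  }

  out <- aggregate_rows(responses)
  subgroups <- NULL
  if (!is.null(age)) {
    over <- responses[age > 60, , drop = FALSE]
    under <- responses[age < 60, , drop = FALSE]
    subgroups <- list()
    if (nrow(over) > 0L) subgroups[["over_60"]] <- aggregate_rows(over)
    if (nrow(under) > 0L) subgroups[["under_60"]] <- aggregate_rows(under)
  }
  structure(c(out, list(subgroups = subgroups)),
            class = "lab_acceptance_scores")
}

#' @export
print.lab_acceptance_scores <- function(x, ...) {
  cat(sprintf("Acceptance scores over %d respondent(s):\n", x$n))
  for (i in seq_len(nrow(x$criteria))) {
    cat(sprintf("  %-5s mean %.1f\n", x$criteria$criterion[i],
                x$criteria$mean[i]))
  }
  invisible(x)
}

#' Percentage from a count ratio
#'
#' `100 * numerator / denominator`, e.g. a recruitment rate from invited
#' and enrolled counts.
#'
#' @param numerator Non-negative count, at most `denominator`.
#' @param denominator Positive count.
#' @return Percentage value.
#' @export
#' @examples
#' proportion(120, 500)  # 24
proportion <- function(numerator, denominator) {
  if (!is_scalar_number(denominator) || denominator <= 0) {
    stop_labdss("denominator must be a positive count", "labdss_domain_error")
  }
  if (!is_scalar_number(numerator) || numerator < 0 ||
      numerator > denominator) {
    stop_labdss("numerator must be a count in [0, denominator]",
                "labdss_domain_error")
  }
  100 * numerator / denominator
}
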