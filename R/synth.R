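# Packaged fixtures and seeded synthetic-data generators, so every module
# is testable without any external data source.

#' Paths of the packaged fixtures
#'
#' The package ships small JSON fixtures covering the worked inference
#' example and the rule-catalogue facts:
#' \describe{
#'   \item{blood_sugar_kb}{A blood-sugar knowledge base whose rule chain
#'     ends in rule id `"4785"` emitting artefact id `"4786"`. The rule
#'     thresholds follow common glycemia conventions and are synthetic:
#'     only the endpoint identifiers and the component list are fixed by
#'     the worked example this fixture mirrors.}
#'   \item{blood_sugar_bundle}{The matching order bundle of five
#'     observations: HbA1c in mmol/mol and in %, haemoglobin, plasma
#'     glucose (mmol/L), and C-peptide (pmol/L).}
#'   \item{cbc_test}{A complete-blood-count test definition with exactly
#'     22 atomic components (standard haematology panel; reference
#'     intervals are synthetic adult values).}
#'   \item{icd10_catalogue}{An artefact catalogue carrying the 14 ICD-10
#'     rule-group codes the production system covers (kidney, liver,
#'     pancreas, thyroid, red/white blood cells, prostate).}
#' }
#'
#' @return Named character vector of file paths.
#' @export
#' @examples
#' fx <- packaged_fixtures()
#' names(fx)
packaged_fixtures <- function() {
  names <- c("blood_sugar_kb", "blood_sugar_bundle", "cbc_test",
             "icd10_catalogue")
  files <- c("blood_sugar_kb.json", "blood_sugar_bundle.json",
             "cbc_test.json", "icd10_catalogue.json")
  paths <- vapply(files, function(f) {
    system.file("extdata", f, package = "labdss", mustWork = TRUE)
  }, character(1))
  stats::setNames(paths, names)
}

#' Read a test definition fixture
#'
#' @param path Path to a test-definition JSON file (e.g. the `cbc_test`
#'   fixture).
#' @return A `lab_test_definition`.
#' @export
read_test_definition <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lab_test_definition(
    test_id = x$test_id %||% "", name = x$name %||% "",
    components = lapply(x$components %||% list(), function(cmp) {
      test_component(cmp$code %||% "", cmp$name %||% "", cmp$unit %||% "",
                     cmp$reference_low, cmp$reference_high)
    })
  )
}

#' Read an artefact catalogue fixture
#'
#' @param path Path to an artefact-catalogue JSON file (an array of
#'   artefact objects).
#' @return Named list of [artefact()] objects.
#' @export
read_artefact_catalogue <- function(path) {
  xs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  arts <- lapply(xs, function(a) {
    artefact(a$artefact_id %||% "", a$text %||% "",
             unlist(a$icd10_codes %||% list()),
             isTRUE(a$sensitive), unlist(a$categories %||% list()))
  })
  stats::setNames(arts, vapply(arts, function(a) a$artefact_id, character(1)))
}

#' Configuration for the synthetic generators
#'
#' @param seed Integer seed; all generators are pure functions of their
#'   configuration and seed.
#' @param n Number of items (bundles, reports, respondents) to generate.
#' @param abnormal_fraction Probability that a generated component value
#'   falls outside its reference interval.
#' @param disagreement_rate Probability that the two synthetic raters
#'   disagree on a report.
#' @param likert_means Named numeric vector of per-item target means in
#'   `[1, 7]` for survey generation.
#' @return An object of class `lab_generator_config`.
#' @export
generator_config <- function(seed = 1L, n = 10L, abnormal_fraction = 0.3,
                             disagreement_rate = 0, likert_means = NULL) {
  if (n <= 0) stop_labdss("n must be positive", "labdss_domain_error")
  if (abnormal_fraction < 0 || abnormal_fraction > 1) {
    stop_labdss("abnormal_fraction must be in [0, 1]", "labdss_domain_error")
  }
  if (disagreement_rate < 0 || disagreement_rate > 1) {
    stop_labdss("disagreement_rate must be in [0, 1]", "labdss_domain_error")
  }
  structure(list(
    seed = as.integer(seed), n = as.integer(n),
    abnormal_fraction = abnormal_fraction,
    disagreement_rate = disagreement_rate,
    likert_means = likert_means
  ), class = "lab_generator_config")
}

# Independent three-valued evaluation used to record the generator's
# ground truth: numeric Kleene encoding (FALSE = 0, UNKNOWN = 0.5,
# TRUE = 1) with AND = min, OR = max, NOT = 1 - x. Deliberately a
# different construction from the engine's evaluator so the end-to-end
# agreement check is a genuine cross-validation.
naive_expr_value <- function(expr, values) {
  if (expr$kind == "LEAF") {
    cond <- expr$condition
    v <- values[[cond$component_code]]
    if (is.null(v) || is.na(v)) return(0.5)
    res <- switch(cond$operator,
      EQ = abs(v - cond$operand_eq) <= EQ_TOLERANCE,
      NE = abs(v - cond$operand_eq) > EQ_TOLERANCE,
      INCLUDES = v >= cond$operand_low && v <= cond$operand_high,
      EXCLUDES = v < cond$operand_low || v > cond$operand_high
    )
    return(as.numeric(res))
  }
  child_vals <- vapply(expr$children, naive_expr_value, numeric(1), values)
  switch(expr$kind,
         AND = min(child_vals),
         OR = max(child_vals),
         NOT = 1 - child_vals[[1]])
}

# Which production rules should emit an artefact given exact component
# values, accounting for exclusions. Shared by the generator's
# ground-truth recording.
naive_expected_rules <- function(kb, test_ids, values) {
  fired <- character()
  for (test_id in test_ids) {
    cfg <- kb$configurations[[test_id]]
    if (is.null(cfg)) next
    for (rule_id in cfg$direct_rule_ids) {
      rule <- kb$rules[[rule_id]]
      if (!identical(rule$status, "PRODUCTION")) next
      if (naive_expr_value(rule$expr, values) != 1) next
      excluded <- FALSE
      for (ex in kb$exclusions) {
        if (rule_id %in% ex$target_rule_ids &&
            naive_expr_value(ex$expr, values) == 1) {
          excluded <- TRUE
          break
        }
      }
      if (!excluded) fired <- c(fired, rule_id)
    }
  }
  fired
}

# Default value band for components lacking a reference interval; such
# draws are flagged in the generator output.
DEFAULT_VALUE_BAND <- c(0, 100)

#' Generate random order bundles with ground truth
#'
#' Emulates the random-report validation protocol: for every configured
#' test in the knowledge base, each component value is drawn uniformly
#' inside its reference interval with probability
#' `1 - abnormal_fraction`, otherwise uniformly in a band extending one
#' interval width beyond a randomly chosen bound. Components without a
#' reference interval draw from the default band `[0, 100]` and are
#' flagged. Alongside each bundle the generator records which production
#' rules should fire (net of exclusions), computed by an evaluator
#' independent of the inference engine — so engine output can be checked
#' against generator intent end-to-end.
#'
#' @param kb A validated `lab_kb`.
#' @param config A [generator_config()]; `seed`, `n` and
#'   `abnormal_fraction` are used.
#' @return A list with elements `bundles` (list of `lab_order_bundle`),
#'   `expected_rules` (list of character vectors of rule ids expected to
#'   emit artefacts) and `unbounded_components` (codes that used the
#'   default band).
#' @export
#' @examples
#' kb <- load_knowledge_base(packaged_fixtures()[["blood_sugar_kb"]])
#' gen <- generate_bundles(kb, generator_config(seed = 42, n = 3))
#' length(gen$bundles)
generate_bundles <- function(kb, config) {
  report <- validate_knowledge_base(kb)
  if (validation_errors(report) > 0L) {
    stop_labdss("knowledge base must validate before generation",
                "labdss_validation_error")
  }
  set.seed(config$seed)
  test_ids <- names(kb$configurations)
  unbounded <- character()

  bundles <- vector("list", config$n)
  expected <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    values <- list()
    obs <- list()
    for (test_id in test_ids) {
      for (cmp in kb$tests[[test_id]]$components) {
        has_interval <- !is.null(cmp$reference_low) &&
          !is.null(cmp$reference_high)
        if (!has_interval) {
          unbounded <- union(unbounded, cmp$code)
          v <- runif(1, DEFAULT_VALUE_BAND[1], DEFAULT_VALUE_BAND[2])
        } else if (runif(1) < config$abnormal_fraction) {
          width <- cmp$reference_high - cmp$reference_low
          if (runif(1) < 0.5) {
            v <- runif(1, cmp$reference_low - width, cmp$reference_low)
          } else {
            v <- runif(1, cmp$reference_high, cmp$reference_high + width)
          }
          # the interval is closed, so nudge boundary draws outside it
          if (v >= cmp$reference_low && v <= cmp$reference_high) {
            v <- cmp$reference_high + width / 2
          }
        } else {
          v <- runif(1, cmp$reference_low, cmp$reference_high)
        }
        values[[cmp$code]] <- v
        obs[[length(obs) + 1L]] <- observation(
          cmp$code, v, cmp$unit,
          sprintf("2024-01-01T%02d:00:00Z", length(obs) %% 24)
        )
      }
    }
    bundles[[i]] <- order_bundle(
      order_id = sprintf("synthetic-%04d", i),
      patient = patient(sprintf("patient-%04d", i),
                        if (runif(1) < 0.5) "FEMALE" else "MALE"),
      observations = obs,
      ordered_test_ids = test_ids
    )
    expected[[i]] <- naive_expected_rules(kb, test_ids, values)
  }
  list(bundles = bundles, expected_rules = expected,
       unbounded_components = unbounded)
}

#' Generate synthetic rater labels for report validation
#'
#' Emulates a two-expert review of `n` generated reports: each report's
#' consensus label is `INCORRECT` with probability `error_rate`, and each
#' rater independently deviates from consensus with probability
#' `disagreement_rate / 2` (so the two raters disagree with each other at
#' roughly `disagreement_rate`).
#'
#' @param n Number of reports.
#' @param error_rate Expected fraction of incorrect reports.
#' @param disagreement_rate Expected rater-vs-rater disagreement rate.
#' @param seed Integer seed.
#' @return An object of class `lab_labeled_reports`: a data frame with
#'   columns `report_id`, `rater_a`, `rater_b`, `consensus`.
#' @export
#' @examples
#' labels <- generate_rater_labels(100, error_rate = 0.05,
#'                                 disagreement_rate = 0.02, seed = 7)
#' table(labels$consensus)
generate_rater_labels <- function(n, error_rate, disagreement_rate, seed) {
  if (n <= 0) stop_labdss("n must be positive", "labdss_domain_error")
  for (r in c(error_rate, disagreement_rate)) {
    if (r < 0 || r > 1) {
      stop_labdss("rates must be in [0, 1]", "labdss_domain_error")
    }
  }
  set.seed(as.integer(seed))
  consensus <- ifelse(runif(n) < error_rate, "INCORRECT", "CORRECT")
  flip <- function(labels, p) {
    do_flip <- runif(n) < p
    ifelse(do_flip,
           ifelse(labels == "CORRECT", "INCORRECT", "CORRECT"),
           labels)
  }
  out <- data.frame(
    report_id = sprintf("report-%04d", seq_len(n)),
    rater_a = flip(consensus, disagreement_rate / 2),
    rater_b = flip(consensus, disagreement_rate / 2),
    consensus = consensus,
    stringsAsFactors = FALSE
  )
  class(out) <- c("lab_labeled_reports", class(out))
  out
}

#' Generate synthetic Likert survey responses
#'
#' Draws integer responses in `[1, 7]` per item as
#' `1 + Binomial(6, (target - 1) / 6)`, whose expectation equals the
#' target mean exactly; realised item means therefore sit within
#' binomial sampling error of the targets. A target of 1 or 7 yields a
#' constant column.
#'
#' @param n_respondents Number of respondents.
#' @param likert_means Named numeric vector of target item means in
#'   `[1, 7]`; names become response columns.
#' @param seed Integer seed.
#' @return Data frame with a `respondent` column and one integer column
#'   per item.
#' @export
#' @examples
#' generate_survey(5, c(BI1 = 5.7, BI2 = 6.1), seed = 3)
generate_survey <- function(n_respondents, likert_means, seed) {
  if (n_respondents <= 0) {
    stop_labdss("n_respondents must be positive", "labdss_domain_error")
  }
  if (is.null(names(likert_means)) || any(!nzchar(names(likert_means)))) {
    stop_labdss("likert_means must be a named vector", "labdss_domain_error")
  }
  if (any(likert_means < 1 | likert_means > 7)) {
    stop_labdss("target means must be in [1, 7]", "labdss_domain_error")
  }
  set.seed(as.integer(seed))
  out <- data.frame(respondent = seq_len(n_respondents))
  for (item in names(likert_means)) {
    p <- (likert_means[[item]] - 1) / 6
    out[[item]] <- 1L + rbinom(n_respondents, 6L, p)
  }
  out
}
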