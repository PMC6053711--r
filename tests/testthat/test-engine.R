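test_that("condition operators follow closed-in/open-out interval semantics", {
  inc <- condition("glucose", "INCLUDES", 4.0, 6.2)
  exc <- condition("glucose", "EXCLUDES", 4.0, 6.2)
  expect_identical(evaluate_condition(inc, 5.0), "TRUE")
  expect_identical(evaluate_condition(exc, 5.0), "FALSE")
  # boundaries belong to the interval
  expect_identical(evaluate_condition(inc, 6.2), "TRUE")
  expect_identical(evaluate_condition(exc, 6.2), "FALSE")
  expect_identical(evaluate_condition(exc, 6.3), "TRUE")

  # INCLUDES and EXCLUDES are complementary for any finite value
  set.seed(5)
  for (v in runif(50, 0, 10)) {
    expect_false(identical(evaluate_condition(inc, v),
                           evaluate_condition(exc, v)))
  }

  eq <- condition("x", "EQ", operand_eq = 5)
  ne <- condition("x", "NE", operand_eq = 5)
  expect_identical(evaluate_condition(eq, 5 + 1e-12), "TRUE")
  expect_identical(evaluate_condition(ne, 5 + 1e-12), "FALSE")
  expect_identical(evaluate_condition(eq, 5.001), "FALSE")

  # missing values are UNKNOWN under every operator
  for (cond in list(inc, exc, eq, ne)) {
    expect_identical(evaluate_condition(cond, NA), "UNKNOWN")
  }
})

test_that("expression evaluation matches the Kleene truth table exhaustively", {
  tv_levels <- c(0, 0.5, 1)  # FALSE, UNKNOWN, TRUE in the oracle encoding
  # leaves on distinct components; assignments steer each leaf's outcome
  leaf <- function(code) expr_leaf(condition(code, "INCLUDES", 0, 1))
  value_for <- function(tv) switch(as.character(tv),
                                   "0" = 2, "0.5" = NA_real_, "1" = 0.5)
  l1 <- leaf("k1"); l2 <- leaf("k2"); l3 <- leaf("k3")

  shapes <- list(
    list(expr = expr_not(l1), n = 1),
    list(expr = expr_and(l1, l2), n = 2),
    list(expr = expr_or(l1, l2), n = 2),
    list(expr = expr_and(expr_not(l1), l2), n = 2),
    list(expr = expr_or(l1, expr_not(l2)), n = 2),
    list(expr = expr_not(expr_and(l1, l2)), n = 2),
    list(expr = expr_not(expr_or(l1, l2)), n = 2),
    list(expr = expr_and(l1, l2, l3), n = 3),
    list(expr = expr_or(l1, l2, l3), n = 3),
    list(expr = expr_and(l1, expr_or(l2, l3)), n = 3),
    list(expr = expr_or(l1, expr_and(l2, l3)), n = 3),
    list(expr = expr_and(expr_not(l1), expr_or(l2, expr_not(l3))), n = 3),
    list(expr = expr_not(expr_or(l1, expr_and(l2, l3))), n = 3)
  )
  for (shape in shapes) {
    grid <- expand.grid(rep(list(tv_levels), shape$n))
    for (row in seq_len(nrow(grid))) {
      tvs <- as.numeric(grid[row, ])
      leaf_values <- stats::setNames(as.list(tvs),
                                     c("k1", "k2", "k3")[seq_len(shape$n)])
      resolver_values <- lapply(tvs, value_for)
      names(resolver_values) <- names(leaf_values)
      resolver <- function(code) resolver_values[[code]]
      expect_identical(
        evaluate_expr(shape$expr, resolver),
        oracle_expr(shape$expr, leaf_values),
        info = sprintf("shape %d assignment %s", which(
          vapply(shapes, identical, logical(1), shape)
        ), paste(tvs, collapse = ","))
      )
    }
  }
})

test_that("the worked example emits artefact 4786 from rule 4785", {
  kb <- load_knowledge_base(fixture_paths[["blood_sugar_kb"]])
  bundle <- read_order_bundle(fixture_paths[["blood_sugar_bundle"]])
  res <- run_inference(kb, bundle)
  expect_identical(emitted_rule_ids(res), "4785")
  expect_identical(emitted_artefact_ids(res), "4786")

  # trace covers every configured rule: fired, not fired, or skipped draft
  direct <- Filter(function(s) s$rule_kind == "DIRECT", res$trace)
  expect_setequal(vapply(direct, function(s) s$rule_id, character(1)),
                  kb$configurations[["blood_sugar"]]$direct_rule_ids)
  skipped <- Filter(function(s) isTRUE(s$skipped), direct)
  expect_identical(vapply(skipped, function(s) s$rule_id, character(1)),
                   "4789")
})

test_that("an effective exclusion vetoes the artefact and appears in the trace", {
  kb <- load_knowledge_base(fixture_paths[["blood_sugar_kb"]])
  bundle <- read_order_bundle(fixture_paths[["blood_sugar_bundle"]])
  # drive haemoglobin into the exclusion band of rule 4785
  bundle$observations <- lapply(bundle$observations, function(o) {
    if (o$component_code == "hb") o$value <- 4.0
    o
  })
  res <- run_inference(kb, bundle)
  expect_length(res$artefacts, 0)
  direct <- Filter(function(s) s$rule_id == "4785" && s$rule_kind == "DIRECT",
                   res$trace)
  expect_length(direct, 1)
  expect_true(direct[[1]]$fired)
  expect_true(direct[[1]]$excluded)
  excl <- Filter(function(s) s$rule_kind == "EXCLUSION", res$trace)
  expect_length(excl, 1)
  expect_true(excl[[1]]$fired)
})

test_that("an empty bundle fires nothing and traces all-UNKNOWN evaluations", {
  kb <- load_knowledge_base(fixture_paths[["blood_sugar_kb"]])
  bundle <- order_bundle("o-empty", patient("p"), list(), "blood_sugar")
  res <- run_inference(kb, bundle)
  expect_length(res$artefacts, 0)
  evaluated <- Filter(function(s) !isTRUE(s$skipped), res$trace)
  expect_gt(length(evaluated), 0)
  for (step in evaluated) {
    expect_false(step$fired)
    outcomes <- vapply(step$condition_values, function(cv) cv$outcome,
                       character(1))
    expect_true(all(outcomes == "UNKNOWN"))
  }
})

test_that("inference refuses an invalid knowledge base", {
  kb <- mini_kb()
  kb$rules[["r1"]]$artefact_id <- "missing"
  expect_error(run_inference(kb, mini_bundle(a = 25)),
               class = "labdss_validation_error")
})

test_that("inference is deterministic and reorder-invariant", {
  kb <- load_knowledge_base(fixture_paths[["blood_sugar_kb"]])
  bundle <- read_order_bundle(fixture_paths[["blood_sugar_bundle"]])
  r1 <- run_inference(kb, bundle)
  r2 <- run_inference(kb, bundle)
  expect_identical(r1, r2)
  shuffled <- bundle
  shuffled$observations <- rev(bundle$observations)
  r3 <- run_inference(kb, shuffled)
  expect_identical(r1$artefacts, r3$artefacts)
  expect_identical(r1$trace, r3$trace)
})

test_that("adding an exclusion never increases the artefact count", {
  set.seed(101)
  for (i in 1:60) {
    kb <- random_kb(n_rules = sample(1:4, 1), n_exclusions = 0)
    bundle <- random_bundle()
    before <- length(run_inference(kb, bundle)$artefacts)
    kb$exclusions <- list(exclusion_rule("extra",
                                         sample(names(kb$rules), 1),
                                         random_expr()))
    after <- length(run_inference(kb, bundle)$artefacts)
    expect_lte(after, before)
  }
})

test_that("engine output matches the naive unindexed oracle on random inputs", {
  set.seed(202)
  for (i in 1:80) {
    kb <- random_kb()
    bundle <- random_bundle()
    res <- run_inference(kb, bundle)
    expect_identical(sort(emitted_artefact_ids(res)),
                     sort(oracle_inference(kb, bundle)),
                     info = sprintf("case %d", i))
    # trace completeness: one evaluated DIRECT step per production rule
    direct <- Filter(function(s) s$rule_kind == "DIRECT" && !isTRUE(s$skipped),
                     res$trace)
    n_prod <- sum(vapply(kb$rules, function(r) {
      identical(r$status, "PRODUCTION")
    }, logical(1)))
    expect_length(direct, n_prod)
  }
})

test_that("explanations are pure, complete and ordered", {
  kb <- load_knowledge_base(fixture_paths[["blood_sugar_kb"]])
  bundle <- read_order_bundle(fixture_paths[["blood_sugar_bundle"]])
  res <- run_inference(kb, bundle)
  doc <- explain(res)
  expect_identical(doc, explain(res))
  # every trace step appears exactly once, in order
  step_lines <- grep("^\\[(DIRECT|EXCLUSION) rule ", unclass(doc),
                     value = TRUE)
  expect_length(step_lines, length(res$trace))
  ids <- sub("^\\[(DIRECT|EXCLUSION) rule ([^]]+)\\].*$", "\\2", step_lines)
  expect_identical(ids, vapply(res$trace, function(s) s$rule_id,
                               character(1)))
  expect_true(any(grepl("artefact 4786", unclass(doc))))
  # the fired rule's conditions show observed values
  expect_true(any(grepl("observed: 7.8", unclass(doc), fixed = TRUE)))

  # an empty trace renders without failure
  empty <- run_inference(kb, order_bundle("o", patient("p"), list(),
                                          character()))
  expect_s3_class(explain(empty), "lab_explanation")
})

test_that("inference results serialise to the conclusion-array document", {
  kb <- load_knowledge_base(fixture_paths[["blood_sugar_kb"]])
  bundle <- read_order_bundle(fixture_paths[["blood_sugar_bundle"]])
  res <- run_inference(kb, bundle)
  out <- withr::local_tempfile(fileext = ".json")
  trace_out <- withr::local_tempfile(fileext = ".json")
  write_inference_result(res, out, trace_path = trace_out)
  doc <- jsonlite::fromJSON(out, simplifyVector = FALSE)
  expect_identical(doc$order_id, "ord-2024-0001")
  expect_length(doc$conclusions, 1)
  expect_identical(doc$conclusions[[1]]$rule_id, "4785")
  expect_identical(doc$conclusions[[1]]$artefact_id, "4786")
  expect_true(nzchar(doc$conclusions[[1]]$text))
  trace_doc <- jsonlite::fromJSON(trace_out, simplifyVector = FALSE)
  expect_length(trace_doc$trace, length(res$trace))
})
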