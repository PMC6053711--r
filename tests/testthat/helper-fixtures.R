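# Shared builders: a small in-code knowledge base, random knowledge-base /
# bundle generators for property tests, and independent oracles.

fixture_paths <- packaged_fixtures()

mini_kb <- function() {
  knowledge_base(
    version = "test",
    tests = list(lab_test_definition(
      "panel", "Test Panel",
      list(
        test_component("a", "Analyte A", "mmol/L", 10, 20),
        test_component("b", "Analyte B", "U/L", 0, 5),
        test_component("c", "Analyte C", "g/L")
      )
    )),
    configurations = list(test_configuration("panel", c("r1", "r2", "r3"))),
    rules = list(
      direct_rule("r1", "panel",
                  expr_leaf(condition("a", "EXCLUDES", 10, 20)),
                  artefact_id = "art1", status = "PRODUCTION",
                  author = "alice", reviewer = "bob"),
      direct_rule("r2", "panel",
                  expr_and(expr_leaf(condition("a", "INCLUDES", 10, 20)),
                           expr_leaf(condition("b", "EXCLUDES", 0, 5))),
                  artefact_id = "art2", status = "PRODUCTION",
                  author = "bob", reviewer = "alice"),
      direct_rule("r3", "panel",
                  expr_leaf(condition("c", "EQ", operand_eq = 1)),
                  artefact_id = "art1", status = "DRAFT", author = "alice")
    ),
    exclusions = list(
      exclusion_rule("x1", "r1",
                     expr_leaf(condition("b", "EXCLUDES", 0, 5)))
    ),
    artefacts = list(
      artefact("art1", "Analyte A is outside its reference interval; this may be worth discussing with your physician."),
      artefact("art2", "A combined pattern in analytes A and B was observed; please discuss it with your physician.",
               icd10_codes = "E11")
    )
  )
}

mini_bundle <- function(a = NULL, b = NULL, c_ = NULL, order_id = "ord-1") {
  obs <- list()
  if (!is.null(a)) obs <- c(obs, list(observation("a", a, "mmol/L")))
  if (!is.null(b)) obs <- c(obs, list(observation("b", b, "U/L")))
  if (!is.null(c_)) obs <- c(obs, list(observation("c", c_, "g/L")))
  order_bundle(order_id, patient("p-1", "FEMALE"), obs, "panel")
}

emitted_artefact_ids <- function(result) {
  vapply(result$artefacts, function(a) a$artefact_id, character(1))
}

emitted_rule_ids <- function(result) {
  vapply(result$artefacts, function(a) a$rule_id, character(1))
}

## ---- random generators for property tests ---------------------------------

RANDOM_COMPONENTS <- list(
  test_component("c1", "Component 1", "u1", 10, 20),
  test_component("c2", "Component 2", "u2", 0, 5),
  test_component("c3", "Component 3", "u3", 100, 200)
)

random_condition <- function() {
  cmp <- RANDOM_COMPONENTS[[sample(3, 1)]]
  op <- sample(c("EQ", "NE", "INCLUDES", "EXCLUDES"), 1)
  span <- cmp$reference_high - cmp$reference_low
  lo <- cmp$reference_low - span
  hi <- cmp$reference_high + span
  if (op %in% c("EQ", "NE")) {
    condition(cmp$code, op, operand_eq = round(runif(1, lo, hi), 1))
  } else {
    bounds <- sort(round(runif(2, lo, hi), 1))
    condition(cmp$code, op, bounds[1], bounds[2])
  }
}

random_expr <- function(depth = 2) {
  if (depth <= 0 || runif(1) < 0.45) {
    return(expr_leaf(random_condition()))
  }
  kind <- sample(c("AND", "OR", "NOT"), 1)
  if (kind == "NOT") {
    expr_not(random_expr(depth - 1))
  } else {
    children <- lapply(seq_len(sample(2:3, 1)), function(i) {
      random_expr(depth - 1)
    })
    do.call(if (kind == "AND") expr_and else expr_or, children)
  }
}

random_kb <- function(n_rules = sample(1:5, 1),
                      n_exclusions = sample(0:2, 1)) {
  rule_ids <- paste0("rule", seq_len(n_rules))
  rules <- lapply(rule_ids, function(rid) {
    direct_rule(rid, "rt", random_expr(), artefact_id = paste0("art_", rid),
                status = "PRODUCTION", author = "a", reviewer = "b")
  })
  arts <- lapply(rule_ids, function(rid) {
    artefact(paste0("art_", rid),
             sprintf("Synthetic recommendation for %s; discuss with your physician.", rid))
  })
  exclusions <- lapply(seq_len(n_exclusions), function(i) {
    targets <- sample(rule_ids, sample(seq_along(rule_ids), 1))
    exclusion_rule(paste0("ex", i), targets, random_expr())
  })
  knowledge_base(
    version = "random",
    tests = list(lab_test_definition("rt", "Random Test", RANDOM_COMPONENTS)),
    configurations = list(test_configuration("rt", rule_ids)),
    rules = rules,
    exclusions = exclusions,
    artefacts = arts
  )
}

random_bundle <- function(max_obs = 6) {
  n <- sample(0:max_obs, 1)
  obs <- lapply(seq_len(n), function(i) {
    cmp <- RANDOM_COMPONENTS[[sample(3, 1)]]
    span <- cmp$reference_high - cmp$reference_low
    observation(cmp$code,
                round(runif(1, cmp$reference_low - span,
                            cmp$reference_high + span), 2),
                cmp$unit,
                sprintf("2024-01-01T00:%02d:00Z", i))
  })
  order_bundle("rnd", patient("p"), obs, "rt")
}

## ---- independent oracles ---------------------------------------------------

# Kleene logic by numeric encoding FALSE = 0, UNKNOWN = 0.5, TRUE = 1:
# AND = min, OR = max, NOT = 1 - x. Independent of the engine's
# string-based recursive evaluator.
oracle_expr <- function(expr, leaf_values) {
  walk <- function(node) {
    if (node$kind == "LEAF") {
      return(leaf_values[[node$condition$component_code]])
    }
    vals <- vapply(node$children, walk, numeric(1))
    switch(node$kind, AND = min(vals), OR = max(vals), NOT = 1 - vals[[1]])
  }
  c("FALSE", "UNKNOWN", "TRUE")[2 * walk(expr) + 1]
}

# Naive inference oracle: no indexing, no configuration machinery — for
# every rule in the kb, resolve each leaf's value straight from the
# observation list and evaluate with the numeric-Kleene oracle, then
# veto via exclusions the same way. Returns the emitted artefact ids.
oracle_inference <- function(kb, bundle) {
  values <- list()
  for (t in kb$tests) {
    for (cmp in t$components) {
      v <- NA_real_
      stamp <- NULL
      for (o in bundle$observations) {
        if (identical(o$component_code, cmp$code) &&
            identical(o$unit, cmp$unit)) {
          s <- if (is.null(o$observed_at)) "" else o$observed_at
          if (is.null(stamp) || s >= stamp) {
            v <- o$value
            stamp <- s
          }
        }
      }
      values[[cmp$code]] <- v
    }
  }
  tv <- function(expr) {
    walk <- function(node) {
      if (node$kind == "LEAF") {
        cond <- node$condition
        val <- values[[cond$component_code]]
        if (is.null(val) || is.na(val)) return(0.5)
        hit <- switch(cond$operator,
          EQ = abs(val - cond$operand_eq) <= 1e-9,
          NE = abs(val - cond$operand_eq) > 1e-9,
          INCLUDES = val >= cond$operand_low && val <= cond$operand_high,
          EXCLUDES = val < cond$operand_low || val > cond$operand_high)
        return(as.numeric(hit))
      }
      vals <- vapply(node$children, walk, numeric(1))
      switch(node$kind, AND = min(vals), OR = max(vals), NOT = 1 - vals[[1]])
    }
    walk(expr)
  }
  emitted <- character()
  matched <- unique(bundle$ordered_test_ids)
  matched <- matched[matched %in% names(kb$configurations)]
  for (rule in kb$rules) {
    if (!rule$status == "PRODUCTION") next
    if (!rule$test_id %in% matched) next
    in_config <- rule$rule_id %in%
      kb$configurations[[rule$test_id]]$direct_rule_ids
    if (!in_config) next
    if (tv(rule$expr) != 1) next
    vetoed <- FALSE
    for (ex in kb$exclusions) {
      if (rule$rule_id %in% ex$target_rule_ids && tv(ex$expr) == 1) {
        vetoed <- TRUE
      }
    }
    if (!vetoed) emitted <- c(emitted, rule$artefact_id)
  }
  emitted
}

# Brute-force Cohen's kappa from the contingency-table definition.
oracle_kappa <- function(a, b) {
  cats <- union(a, b)
  n <- length(a)
  tab <- matrix(0, length(cats), length(cats),
                dimnames = list(cats, cats))
  for (i in seq_len(n)) tab[a[i], b[i]] <- tab[a[i], b[i]] + 1
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}
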