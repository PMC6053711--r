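# Forward-chaining inference over direct and exclusion rules, with a
# complete explanation trace. Conditions evaluate under Kleene
# three-valued logic so a missing observation neither fires a direct rule
# nor triggers an exclusion (fail-safe behaviour on partial bundles).

#' Evaluate one condition against a value
#'
#' Missing values (`NA`) evaluate to `"UNKNOWN"`. `EQ`/`NE` compare
#' within an absolute tolerance of `1e-9`; `INCLUDES` tests closed
#' interval membership `low <= value <= high`; `EXCLUDES` is its exact
#' complement, so for any finite value exactly one of the two holds on
#' the same interval.
#'
#' @param cond A [condition()] object.
#' @param value Numeric value or `NA` for an absent observation.
#' @return `"TRUE"`, `"FALSE"` or `"UNKNOWN"`.
#' @export
#' @examples
#' evaluate_condition(condition("glucose", "INCLUDES", 4.0, 6.2), 5.0)
#' evaluate_condition(condition("glucose", "EXCLUDES", 4.0, 6.2), 6.2)
#' evaluate_condition(condition("glucose", "EQ", operand_eq = 5), NA)
evaluate_condition <- function(cond, value) {
  if (is.null(value) || length(value) == 0L || is.na(value)) {
    return(TV_UNKNOWN)
  }
  res <- switch(cond$operator,
    EQ = abs(value - cond$operand_eq) <= EQ_TOLERANCE,
    NE = abs(value - cond$operand_eq) > EQ_TOLERANCE,
    INCLUDES = value >= cond$operand_low && value <= cond$operand_high,
    EXCLUDES = value < cond$operand_low || value > cond$operand_high,
    stop_labdss(sprintf("unknown operator '%s'", cond$operator),
                "labdss_schema_error")
  )
  if (res) TV_TRUE else TV_FALSE
}

#' Evaluate a condition expression under Kleene logic
#'
#' Three-valued semantics: AND is FALSE if any child is FALSE, else
#' UNKNOWN if any child is UNKNOWN, else TRUE; OR is the dual (TRUE
#' dominates); NOT maps UNKNOWN to UNKNOWN.
#'
#' @param expr A `lab_expr` expression tree.
#' @param resolver Function mapping a component code to a numeric value
#'   or `NA` (see [resolve_value()]).
#' @return `"TRUE"`, `"FALSE"` or `"UNKNOWN"`.
#' @export
evaluate_expr <- function(expr, resolver) {
  switch(expr$kind,
    LEAF = evaluate_condition(expr$condition, resolver(expr$condition$component_code)),
    AND = {
      vals <- vapply(expr$children, evaluate_expr, character(1), resolver)
      if (any(vals == TV_FALSE)) TV_FALSE
      else if (any(vals == TV_UNKNOWN)) TV_UNKNOWN
      else TV_TRUE
    },
    OR = {
      vals <- vapply(expr$children, evaluate_expr, character(1), resolver)
      if (any(vals == TV_TRUE)) TV_TRUE
      else if (any(vals == TV_UNKNOWN)) TV_UNKNOWN
      else TV_FALSE
    },
    NOT = {
      v <- evaluate_expr(expr$children[[1]], resolver)
      if (v == TV_TRUE) TV_FALSE else if (v == TV_FALSE) TV_TRUE else TV_UNKNOWN
    },
    stop_labdss(sprintf("unknown expression kind '%s'", expr$kind),
                "labdss_schema_error")
  )
}

describe_condition <- function(cond) {
  switch(cond$operator,
    EQ = sprintf("%s = %g", cond$component_code, cond$operand_eq),
    NE = sprintf("%s <> %g", cond$component_code, cond$operand_eq),
    INCLUDES = sprintf("%s includes [%g, %g]", cond$component_code,
                       cond$operand_low, cond$operand_high),
    EXCLUDES = sprintf("%s excludes [%g, %g]", cond$component_code,
                       cond$operand_low, cond$operand_high),
    sprintf("%s ?", cond$component_code)
  )
}

# Evaluate every leaf of an expression once, for the explanation trace.
collect_condition_values <- function(expr, resolver) {
  if (expr$kind == "LEAF") {
    cond <- expr$condition
    value <- resolver(cond$component_code)
    list(list(
      description = describe_condition(cond),
      component_code = cond$component_code,
      observed = if (is.na(value)) NA_real_ else value,
      outcome = evaluate_condition(cond, value)
    ))
  } else {
    do.call(c, lapply(expr$children, collect_condition_values, resolver))
  }
}

make_resolver <- function(bundle, test_def) {
  units <- stats::setNames(
    vapply(test_def$components, function(c) c$unit, character(1)),
    vapply(test_def$components, function(c) c$code, character(1))
  )
  # values are resolved once per component so repeat lookups (and the
  # unit-mismatch warning) do not multiply across rules
  cache <- new.env(parent = emptyenv())
  function(component_code) {
    if (!component_code %in% names(units)) return(NA_real_)
    if (!is.null(cache[[component_code]])) return(cache[[component_code]])
    v <- resolve_value(bundle, component_code, units[[component_code]])
    cache[[component_code]] <- v
    v
  }
}

trace_step <- function(rule_id, rule_kind, fired, condition_values,
                       skipped = FALSE, excluded = FALSE, note = NULL) {
  structure(list(
    rule_id = rule_id, rule_kind = rule_kind, fired = fired,
    skipped = skipped, excluded = excluded, note = note,
    condition_values = condition_values
  ), class = "lab_trace_step")
}

#' Run inference over a validated knowledge base and an order bundle
#'
#' The inference proceeds in the published order: (1) the bundle's
#' ordered tests are matched against the configurations available in the
#' knowledge base; (2) observation values become facts via
#' [resolve_value()]; (3) for each matched test, the configuration's
#' direct rules are evaluated in list order — only `PRODUCTION` rules
#' participate, others are traced as skipped; (4) when a direct rule's
#' expression is TRUE, every exclusion rule targeting it is evaluated,
#' and the rule's artefact is emitted only if no exclusion is effective;
#' (5) the artefacts and the full evaluation trace form the result.
#'
#' Missing observations propagate as UNKNOWN and never fire a rule nor
#' trigger an exclusion.
#'
#' @param kb A `lab_kb`; must validate with zero errors.
#' @param bundle A `lab_order_bundle`.
#' @return An object of class `lab_inference_result` with fields
#'   `order_id`, `evaluated_test_ids`, `artefacts` (ordered list of
#'   `(rule_id, artefact)` entries) and `trace` (ordered list of trace
#'   steps).
#' @export
#' @examples
#' fx <- packaged_fixtures()
#' kb <- load_knowledge_base(fx[["blood_sugar_kb"]])
#' bundle <- read_order_bundle(fx[["blood_sugar_bundle"]])
#' res <- run_inference(kb, bundle)
#' vapply(res$artefacts, function(a) a$artefact_id, character(1))
run_inference <- function(kb, bundle) {
  report <- validate_knowledge_base(kb)
  if (validation_errors(report) > 0L) {
    stop_labdss("refusing to run inference over an invalid knowledge base",
                "labdss_validation_error")
  }
  tests <- match_tests(kb, bundle)
  trace <- list()
  artefacts <- list()

  for (test_id in tests) {
    cfg <- kb$configurations[[test_id]]
    resolver <- make_resolver(bundle, kb$tests[[test_id]])
    for (rule_id in cfg$direct_rule_ids) {
      rule <- kb$rules[[rule_id]]
      if (!identical(rule$status, "PRODUCTION")) {
        trace[[length(trace) + 1L]] <- trace_step(
          rule_id, "DIRECT", fired = FALSE, condition_values = list(),
          skipped = TRUE,
          note = sprintf("skipped: status %s (not in production)", rule$status)
        )
        next
      }
      cond_values <- collect_condition_values(rule$expr, resolver)
      verdict <- evaluate_expr(rule$expr, resolver)
      fired <- identical(verdict, TV_TRUE)
      excluded <- FALSE
      exclusion_steps <- list()
      if (fired) {
        for (ex in kb$exclusions) {
          if (!rule_id %in% ex$target_rule_ids) next
          ex_values <- collect_condition_values(ex$expr, resolver)
          ex_verdict <- evaluate_expr(ex$expr, resolver)
          effective <- identical(ex_verdict, TV_TRUE)
          if (effective) excluded <- TRUE
          exclusion_steps[[length(exclusion_steps) + 1L]] <- trace_step(
            ex$exclusion_id, "EXCLUSION", fired = effective,
            condition_values = ex_values,
            note = sprintf("targets rule %s", rule_id)
          )
        }
      }
      note <- if (identical(verdict, TV_UNKNOWN)) {
        "missing data: expression UNKNOWN, rule not fired"
      } else if (excluded) {
        "fired but excluded: no artefact emitted"
      }
      trace[[length(trace) + 1L]] <- trace_step(
        rule_id, "DIRECT", fired = fired, condition_values = cond_values,
        excluded = excluded, note = note
      )
      for (step in exclusion_steps) trace[[length(trace) + 1L]] <- step
      if (fired && !excluded) {
        artefacts[[length(artefacts) + 1L]] <- list(
          rule_id = rule_id,
          artefact_id = rule$artefact_id,
          artefact = kb$artefacts[[rule$artefact_id]],
          suppressed = FALSE
        )
      }
    }
  }

  structure(list(
    order_id = bundle$order_id,
    evaluated_test_ids = tests,
    artefacts = artefacts,
    trace = trace
  ), class = "lab_inference_result")
}

#' @export
print.lab_inference_result <- function(x, ...) {
  cat(sprintf("<inference result for order %s: %d artefact(s), %d trace step(s)>\n",
              x$order_id, length(x$artefacts), length(x$trace)))
  for (a in x$artefacts) {
    cat(sprintf("  rule %s -> artefact %s%s\n", a$rule_id, a$artefact_id,
                if (isTRUE(a$suppressed)) " [suppressed]" else ""))
  }
  invisible(x)
}

result_to_list <- function(result) {
  list(
    order_id = result$order_id,
    evaluated_test_ids = as_json_array(result$evaluated_test_ids),
    conclusions = lapply(result$artefacts, function(a) {
      strip_nulls(list(
        rule_id = a$rule_id,
        artefact_id = a$artefact_id,
        text = a$artefact$text,
        icd10_codes = if (!isTRUE(a$suppressed)) {
          as_json_array(a$artefact$icd10_codes)
        } else list(),
        suppressed = a$suppressed,
        referral_notice = a$referral_notice
      ))
    })
  )
}

#' Write an inference result as JSON
#'
#' Emits the result document shape the report generator consumes: an
#' array of conclusion objects each holding the firing rule id, the
#' artefact id and the artefact text.
#'
#' @param result A `lab_inference_result`.
#' @param path Destination file path.
#' @param trace_path Optional path for a companion trace document.
#' @return Invisibly, `path`.
#' @export
write_inference_result <- function(result, path, trace_path = NULL) {
  write_stable_json(result_to_list(result), path)
  if (!is.null(trace_path)) {
    write_stable_json(
      list(order_id = result$order_id,
           trace = lapply(result$trace, function(s) strip_nulls(unclass(s)))),
      trace_path
    )
  }
  invisible(path)
}

#' Render an explanation of an inference result
#'
#' The explanation system renders the ordered sequence of rules the
#' engine evaluated: every trace step appears exactly once, in
#' evaluation order, with each leaf condition's observed value and
#' outcome, so a reviewer can see how each conclusion was (or was not)
#' reached. The rendering is pure: identical results yield identical
#' documents.
#'
#' @param result A `lab_inference_result`.
#' @param ... Unused.
#' @return A character vector of lines, class `lab_explanation`.
#' @export
explain <- function(result, ...) UseMethod("explain")

#' @rdname explain
#' @export
explain.lab_inference_result <- function(result, ...) {
  lines <- c(
    sprintf("Inference explanation for order %s", result$order_id),
    sprintf("Evaluated tests: %s",
            if (length(result$evaluated_test_ids)) {
              paste(result$evaluated_test_ids, collapse = ", ")
            } else "(none)")
  )
  for (step in result$trace) {
    status <- if (step$skipped) "SKIPPED"
      else if (step$fired && isTRUE(step$excluded)) "FIRED (EXCLUDED)"
      else if (step$fired) "FIRED"
      else "NOT FIRED"
    lines <- c(lines, sprintf("[%s rule %s] %s%s",
                              step$rule_kind, step$rule_id, status,
                              if (!is.null(step$note)) {
                                paste0(" - ", step$note)
                              } else ""))
    for (cv in step$condition_values) {
      lines <- c(lines, sprintf(
        "    %s | observed: %s | %s",
        cv$description,
        if (is.na(cv$observed)) "ABSENT" else format(cv$observed),
        cv$outcome
      ))
    }
  }
  for (a in result$artefacts) {
    lines <- c(lines, sprintf(
      "Conclusion: rule %s emitted artefact %s%s",
      a$rule_id, a$artefact_id,
      if (isTRUE(a$suppressed)) " (suppressed by sensitivity policy)" else ""
    ))
  }
  structure(lines, class = "lab_explanation")
}

#' @export
print.lab_explanation <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
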