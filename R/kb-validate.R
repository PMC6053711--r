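#' Validate a knowledge base
#'
#' Checks every structural invariant of the knowledge-base object model:
#' component uniqueness and reference-interval ordering, condition
#' operator arity, expression-tree arity, the 4-eyes constraint on
#' `PRODUCTION` rules (reviewer present and distinct from author),
#' ICD-10 code syntax, and referential integrity across all maps
#' (rule to test, rule to artefact, configuration to rule, exclusion
#' target to rule, condition component to test component).
#'
#' Beyond hard errors, the report carries warnings for suspect but legal
#' content: rules whose `INCLUDES` interval cannot intersect the
#' plausible band of its component (the reference interval widened by
#' one interval width on each side) are flagged as dead rules, and
#' artefacts tagged with sensitivity categories but `sensitive = FALSE`
#' are flagged as inconsistent.
#'
#' @param kb A `lab_kb` object.
#' @return A data frame of class `lab_validation_report` with columns
#'   `severity` (`"error"`/`"warning"`), `path` (location of the
#'   finding) and `message`. Zero error rows means the knowledge base
#'   satisfies every invariant.
#' @export
#' @examples
#' kb <- load_knowledge_base(packaged_fixtures()[["blood_sugar_kb"]])
#' rep <- validate_knowledge_base(kb)
#' sum(rep$severity == "error")
validate_knowledge_base <- function(kb) {
  findings <- list()
  note <- function(severity, path, message) {
    findings[[length(findings) + 1L]] <<- list(
      severity = severity, path = path, message = message
    )
  }
  err <- function(path, message) note("error", path, message)
  warn <- function(path, message) note("warning", path, message)

  if (!inherits(kb, "lab_kb")) {
    err("$", "object is not a knowledge base")
    return(finish_report(findings))
  }

  for (t in kb$tests) {
    tpath <- sprintf("tests[%s]", t$test_id)
    if (length(t$components) == 0L) {
      err(tpath, "test has an empty component list")
    }
    codes <- vapply(t$components, function(c) c$code, character(1))
    dup <- unique(codes[duplicated(codes)])
    for (d in dup) {
      err(tpath, sprintf("duplicate component code '%s'", d))
    }
    for (cmp in t$components) {
      cpath <- sprintf("%s.components[%s]", tpath, cmp$code)
      if (!nzchar(cmp$code)) err(cpath, "component code is empty")
      if (!is.null(cmp$reference_low) && !is.null(cmp$reference_high) &&
          !(cmp$reference_low < cmp$reference_high)) {
        err(cpath, sprintf(
          "reference_low (%g) must be below reference_high (%g)",
          cmp$reference_low, cmp$reference_high
        ))
      }
    }
  }

  for (a in kb$artefacts) {
    apath <- sprintf("artefacts[%s]", a$artefact_id)
    if (!nzchar(trimws(a$text))) err(apath, "artefact text is empty")
    bad <- a$icd10_codes[!grepl("^[A-Z][0-9]+(\\.[0-9]+)?$", a$icd10_codes)]
    for (code in bad) {
      err(apath, sprintf("malformed ICD-10 code '%s'", code))
    }
    if (length(a$categories) > 0L && !a$sensitive) {
      warn(apath, "artefact carries sensitivity categories but sensitive = FALSE")
    }
  }

  for (r in kb$rules) {
    rpath <- sprintf("rules[%s]", r$rule_id)
    if (!r$status %in% RULE_STATUSES) {
      err(rpath, sprintf("unknown status '%s'", r$status))
    }
    if (identical(r$status, "PRODUCTION")) {
      if (is.null(r$reviewer) || !nzchar(r$reviewer)) {
        err(rpath, "4-eyes violation: PRODUCTION rule has no reviewer")
      } else if (identical(r$reviewer, r$author)) {
        err(rpath, "4-eyes violation: reviewer equals author")
      }
    }
    if (!r$test_id %in% names(kb$tests)) {
      err(rpath, sprintf("dangling id: rule '%s' references unknown test '%s'",
                         r$rule_id, r$test_id))
    }
    if (!r$artefact_id %in% names(kb$artefacts)) {
      err(rpath, sprintf(
        "dangling id: rule '%s' references unknown artefact '%s'",
        r$rule_id, r$artefact_id
      ))
    }
    validate_expr(r$expr, rpath, kb, r$test_id, err, warn)
  }

  for (x in kb$exclusions) {
    xpath <- sprintf("exclusions[%s]", x$exclusion_id)
    if (length(x$target_rule_ids) == 0L) {
      err(xpath, "exclusion targets no rules")
    }
    for (tid in x$target_rule_ids) {
      if (!tid %in% names(kb$rules)) {
        err(xpath, sprintf(
          "dangling id: exclusion '%s' targets unknown rule '%s'",
          x$exclusion_id, tid
        ))
      }
    }
    known_tests <- unique(vapply(
      kb$rules[intersect(x$target_rule_ids, names(kb$rules))],
      function(r) r$test_id, character(1)
    ))
    for (tid in known_tests) {
      validate_expr(x$expr, xpath, kb, tid, err, warn, dead_rule = FALSE)
    }
  }

  for (cfg in kb$configurations) {
    cpath <- sprintf("configurations[%s]", cfg$test_id)
    if (!cfg$test_id %in% names(kb$tests)) {
      err(cpath, sprintf("configuration references unknown test '%s'",
                         cfg$test_id))
    }
    for (rid in cfg$direct_rule_ids) {
      if (!rid %in% names(kb$rules)) {
        err(cpath, sprintf(
          "dangling id: configuration '%s' references unknown rule '%s'",
          cfg$test_id, rid
        ))
      } else if (!identical(kb$rules[[rid]]$test_id, cfg$test_id)) {
        err(cpath, sprintf(
          "rule '%s' is scoped to test '%s', not '%s'",
          rid, kb$rules[[rid]]$test_id, cfg$test_id
        ))
      }
    }
  }

  finish_report(findings)
}

finish_report <- function(findings) {
  if (length(findings) == 0L) {
    rep <- data.frame(
      severity = character(), path = character(), message = character(),
      stringsAsFactors = FALSE
    )
  } else {
    rep <- data.frame(
      severity = vapply(findings, `[[`, character(1), "severity"),
      path = vapply(findings, `[[`, character(1), "path"),
      message = vapply(findings, `[[`, character(1), "message"),
      stringsAsFactors = FALSE
    )
  }
  class(rep) <- c("lab_validation_report", class(rep))
  rep
}

#' @export
print.lab_validation_report <- function(x, ...) {
  n_err <- sum(x$severity == "error")
  n_warn <- sum(x$severity == "warning")
  cat(sprintf("<validation report: %d error(s), %d warning(s)>\n",
              n_err, n_warn))
  if (nrow(x) > 0L) {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  [%s] %s: %s\n", x$severity[i], x$path[i], x$message[i]))
    }
  }
  invisible(x)
}

#' Count validation errors
#'
#' @param report A `lab_validation_report`.
#' @return Number of `"error"`-severity findings.
#' @export
validation_errors <- function(report) sum(report$severity == "error")

validate_expr <- function(expr, path, kb, test_id, err, warn,
                          dead_rule = TRUE) {
  if (!is.list(expr) || is.null(expr$kind) || !expr$kind %in% EXPR_KINDS) {
    err(path, "malformed condition expression node")
    return(invisible(NULL))
  }
  if (expr$kind == "LEAF") {
    validate_condition(expr$condition, path, kb, test_id, err, warn, dead_rule)
    return(invisible(NULL))
  }
  n <- length(expr$children)
  if (expr$kind == "NOT" && n != 1L) {
    err(path, sprintf("NOT node must have exactly 1 child, has %d", n))
  }
  if (expr$kind %in% c("AND", "OR") && n < 2L) {
    err(path, sprintf("%s node must have at least 2 children, has %d",
                      expr$kind, n))
  }
  for (child in expr$children) {
    validate_expr(child, path, kb, test_id, err, warn, dead_rule)
  }
  invisible(NULL)
}

validate_condition <- function(cond, path, kb, test_id, err, warn,
                               dead_rule = TRUE) {
  cpath <- sprintf("%s.condition[%s %s]", path,
                   cond$component_code %||% "?", cond$operator %||% "?")
  if (is.null(cond$operator) || !cond$operator %in% CONDITION_OPERATORS) {
    err(cpath, sprintf("unknown operator '%s'", cond$operator %||% ""))
    return(invisible(NULL))
  }
  if (cond$operator %in% c("EQ", "NE")) {
    if (is.null(cond$operand_eq)) {
      err(cpath, sprintf("%s requires operand_eq", cond$operator))
    }
    if (!is.null(cond$operand_low) || !is.null(cond$operand_high)) {
      err(cpath, sprintf("%s must not carry interval operands", cond$operator))
    }
  } else {
    if (is.null(cond$operand_low) || is.null(cond$operand_high)) {
      err(cpath, sprintf("%s requires operand_low and operand_high",
                         cond$operator))
    } else if (!(cond$operand_low <= cond$operand_high)) {
      err(cpath, sprintf("operand_low (%g) must not exceed operand_high (%g)",
                         cond$operand_low, cond$operand_high))
    }
    if (!is.null(cond$operand_eq)) {
      err(cpath, sprintf("%s must not carry operand_eq", cond$operator))
    }
  }

  comp <- find_component(kb, test_id, cond$component_code)
  if (is.null(comp)) {
    err(cpath, sprintf(
      "dangling id: condition references component '%s' absent from test '%s'",
      cond$component_code, test_id
    ))
    return(invisible(NULL))
  }

  # Dead-rule heuristic: an INCLUDES interval that cannot intersect the
  # plausible band (reference interval widened by one width per side) can
  # never fire on a physiologically plausible value.
  if (dead_rule && identical(cond$operator, "INCLUDES") &&
      !is.null(comp$reference_low) && !is.null(comp$reference_high) &&
      !is.null(cond$operand_low) && !is.null(cond$operand_high)) {
    width <- comp$reference_high - comp$reference_low
    band_low <- comp$reference_low - width
    band_high <- comp$reference_high + width
    if (cond$operand_high < band_low || cond$operand_low > band_high) {
      warn(cpath, sprintf(
        "dead rule: INCLUDES [%g, %g] lies outside the plausible band [%g, %g] of '%s'",
        cond$operand_low, cond$operand_high, band_low, band_high,
        cond$component_code
      ))
    }
  }
  invisible(NULL)
}

find_component <- function(kb, test_id, component_code) {
  t <- kb$tests[[test_id]]
  if (is.null(t)) return(NULL)
  for (cmp in t$components) {
    if (identical(cmp$code, component_code)) return(cmp)
  }
  NULL
}
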