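# JSON serialisation of the knowledge base. The on-disk dialect is UTF-8
# with recursively sorted object keys and 2-space indentation so that two
# saves of equal knowledge bases are byte-identical.

strip_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, strip_nulls)
}

sort_keys <- function(x) {
  if (!is.list(x)) return(x)
  if (!is.null(names(x)) && any(nzchar(names(x)))) {
    x <- x[order(names(x))]
  }
  lapply(x, sort_keys)
}

# jsonlite with auto_unbox collapses length-1 character vectors to JSON
# strings; fields that are semantically arrays are wrapped so they always
# serialise as arrays regardless of length.
as_json_array <- function(x) {
  if (length(x) == 0L) return(list())
  lapply(unname(x), identity)
}

write_stable_json <- function(x, path) {
  json <- jsonlite::toJSON(
    sort_keys(strip_nulls(x)),
    auto_unbox = TRUE, pretty = 2, digits = NA, null = "null"
  )
  writeLines(json, path, useBytes = TRUE)
  invisible(NULL)
}

expr_to_list <- function(expr) {
  if (expr$kind == "LEAF") {
    list(kind = "LEAF", condition = unclass(expr$condition))
  } else {
    list(kind = expr$kind, children = lapply(expr$children, expr_to_list))
  }
}

expr_from_list <- function(x) {
  if (is.null(x$kind)) {
    stop_labdss("expression node missing 'kind'", "labdss_schema_error")
  }
  if (identical(x$kind, "LEAF")) {
    c_ <- x$condition
    if (is.null(c_)) {
      stop_labdss("LEAF node missing 'condition'", "labdss_schema_error")
    }
    expr_leaf(condition(
      component_code = c_$component_code %||% "",
      operator = c_$operator %||% "",
      operand_low = c_$operand_low,
      operand_high = c_$operand_high,
      operand_eq = c_$operand_eq
    ))
  } else {
    children <- lapply(x$children %||% list(), expr_from_list)
    structure(list(kind = as.character(x$kind), children = children),
              class = "lab_expr")
  }
}

kb_to_list <- function(kb) {
  list(
    version = kb$version,
    tests = lapply(kb$tests, function(t) {
      list(
        test_id = t$test_id, name = t$name,
        components = lapply(t$components, unclass)
      )
    }),
    configurations = lapply(kb$configurations, function(cfg) {
      list(test_id = cfg$test_id,
           direct_rule_ids = as_json_array(cfg$direct_rule_ids))
    }),
    rules = lapply(kb$rules, function(r) {
      list(
        rule_id = r$rule_id, test_id = r$test_id,
        expr = expr_to_list(r$expr), artefact_id = r$artefact_id,
        status = r$status, author = r$author, reviewer = r$reviewer
      )
    }),
    exclusions = lapply(kb$exclusions, function(x) {
      list(exclusion_id = x$exclusion_id,
           target_rule_ids = as_json_array(x$target_rule_ids),
           expr = expr_to_list(x$expr))
    }),
    artefacts = lapply(kb$artefacts, function(a) {
      list(
        artefact_id = a$artefact_id, text = a$text,
        icd10_codes = as_json_array(a$icd10_codes),
        sensitive = a$sensitive,
        categories = as_json_array(a$categories)
      )
    })
  )
}

kb_from_list <- function(x) {
  req <- function(field) {
    if (is.null(x[[field]])) {
      stop_labdss(sprintf("knowledge-base document missing '%s'", field),
                  "labdss_schema_error")
    }
    x[[field]]
  }
  knowledge_base(
    version = req("version"),
    tests = lapply(unname(req("tests")), function(t) {
      lab_test_definition(
        test_id = t$test_id %||% "", name = t$name %||% "",
        components = lapply(t$components %||% list(), function(cmp) {
          test_component(
            code = cmp$code %||% "", name = cmp$name %||% "",
            unit = cmp$unit %||% "",
            reference_low = cmp$reference_low,
            reference_high = cmp$reference_high
          )
        })
      )
    }),
    configurations = lapply(unname(req("configurations")), function(cfg) {
      test_configuration(
        test_id = cfg$test_id %||% "",
        direct_rule_ids = unlist(cfg$direct_rule_ids %||% list())
      )
    }),
    rules = lapply(unname(req("rules")), function(r) {
      direct_rule(
        rule_id = r$rule_id %||% "", test_id = r$test_id %||% "",
        expr = expr_from_list(r$expr %||% list()),
        artefact_id = r$artefact_id %||% "",
        status = r$status %||% "DRAFT",
        author = r$author %||% "", reviewer = r$reviewer
      )
    }),
    exclusions = lapply(unname(req("exclusions")), function(ex) {
      exclusion_rule(
        exclusion_id = ex$exclusion_id %||% "",
        target_rule_ids = unlist(ex$target_rule_ids %||% list()),
        expr = expr_from_list(ex$expr %||% list())
      )
    }),
    artefacts = lapply(unname(req("artefacts")), function(a) {
      artefact(
        artefact_id = a$artefact_id %||% "", text = a$text %||% "",
        icd10_codes = unlist(a$icd10_codes %||% list()),
        sensitive = isTRUE(a$sensitive),
        categories = unlist(a$categories %||% list())
      )
    })
  )
}

#' Load a knowledge base from a JSON document
#'
#' Parses, reconstructs and validates a knowledge-base document. A
#' document that parses but violates a structural invariant (including
#' any dangling identifier) is rejected with the offending paths in the
#' error message.
#'
#' @param path Path to a knowledge-base JSON file.
#' @return A validated `lab_kb` object.
#' @seealso [save_knowledge_base()], [validate_knowledge_base()]
#' @export
#' @examples
#' kb <- load_knowledge_base(packaged_fixtures()[["blood_sugar_kb"]])
#' names(kb$artefacts)
load_knowledge_base <- function(path) {
  if (!file.exists(path)) {
    stop_labdss(sprintf("knowledge-base file not found: %s", path),
                "labdss_io_error")
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop_labdss(sprintf("malformed knowledge-base document %s: %s",
                          path, conditionMessage(e)),
                  "labdss_parse_error")
    }
  )
  kb <- kb_from_list(parsed)
  report <- validate_knowledge_base(kb)
  if (validation_errors(report) > 0L) {
    bad <- report[report$severity == "error", , drop = FALSE]
    stop_labdss(
      sprintf("knowledge base fails validation (%d error(s)):\n%s",
              nrow(bad),
              paste(sprintf("  %s: %s", bad$path, bad$message),
                    collapse = "\n")),
      "labdss_validation_error"
    )
  }
  kb
}

#' Save a knowledge base as a JSON document
#'
#' Refuses to persist a knowledge base with validation errors, so every
#' saved document loads back cleanly: `load_knowledge_base(path)` on the
#' saved file reconstructs a structurally identical object. Keys are
#' sorted and indentation fixed, making saves of equal knowledge bases
#' byte-identical.
#'
#' @param kb A `lab_kb` object.
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
save_knowledge_base <- function(kb, path) {
  report <- validate_knowledge_base(kb)
  if (validation_errors(report) > 0L) {
    cond <- structure(
      class = c("labdss_validation_error", "labdss_error", "error",
                "condition"),
      list(message = "refusing to save an invalid knowledge base",
           call = sys.call(), report = report)
    )
    stop(cond)
  }
  write_stable_json(kb_to_list(kb), path)
  invisible(path)
}

#' Promote a rule to production (4-eyes review)
#'
#' A rule reaches `PRODUCTION` only after acceptance by a second expert:
#' the reviewer must differ from the rule's author. Promotion is
#' idempotent — promoting an already-`PRODUCTION` rule returns the
#' knowledge base unchanged — and non-destructive: the input object is
#' never modified.
#'
#' @param kb A `lab_kb` object.
#' @param rule_id Identifier of the rule to promote.
#' @param reviewer Name of the accepting expert; must differ from the
#'   rule's author.
#' @return An updated copy of `kb`.
#' @export
#' @examples
#' kb <- load_knowledge_base(packaged_fixtures()[["blood_sugar_kb"]])
#' kb2 <- promote_rule(kb, "4785", reviewer = "second.expert")
#' kb2$rules[["4785"]]$status
promote_rule <- function(kb, rule_id, reviewer) {
  rule <- kb$rules[[rule_id]]
  if (is.null(rule)) {
    stop_labdss(sprintf("rule '%s' not found in knowledge base", rule_id),
                "labdss_not_found_error")
  }
  if (identical(rule$status, "PRODUCTION")) {
    return(kb)
  }
  if (identical(as.character(reviewer), rule$author)) {
    stop_labdss(
      sprintf("self-review forbidden: '%s' authored rule '%s' (4-eyes principle)",
              reviewer, rule_id),
      "labdss_self_review_error"
    )
  }
  rule$status <- "PRODUCTION"
  rule$reviewer <- as.character(reviewer)
  kb$rules[[rule_id]] <- rule
  kb
}
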