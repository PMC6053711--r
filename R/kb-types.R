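#' Define a laboratory test component
#'
#' A component is one atomic measurand of a laboratory test (e.g. plasma
#' glucose within a blood-sugar panel), carrying its display name, unit
#' and optional reference interval against which results are flagged.
#'
#' @param code Opaque identifier, unique within its test.
#' @param name Display name shown on patient reports.
#' @param unit UCUM-style unit string (matched verbatim, no conversion).
#' @param reference_low,reference_high Optional reference-interval bounds;
#'   when both are given `reference_low < reference_high` must hold.
#' @return An object of class `lab_component`.
#' @export
#' @examples
#' test_component("glucose", "Concentration of Glucose in Plasma",
#'                "mmol/L", 4.0, 6.2)
test_component <- function(code, name, unit,
                           reference_low = NULL, reference_high = NULL) {
  structure(list(
    code = as.character(code),
    name = as.character(name),
    unit = as.character(unit),
    reference_low = if (!is.null(reference_low)) as.numeric(reference_low),
    reference_high = if (!is.null(reference_high)) as.numeric(reference_high)
  ), class = "lab_component")
}

#' Define a laboratory test
#'
#' @param test_id Identifier referenced by configurations and rules.
#' @param name Display name.
#' @param components List of [test_component()] objects; must be non-empty
#'   with unique codes.
#' @return An object of class `lab_test_definition`.
#' @export
lab_test_definition <- function(test_id, name, components) {
  structure(list(
    test_id = as.character(test_id),
    name = as.character(name),
    components = unname(components)
  ), class = "lab_test_definition")
}

#' Define an atomic rule condition
#'
#' Conditions compare one component's observed value against operands.
#' `EQ`/`NE` compare to `operand_eq` within an absolute tolerance of
#' `1e-9`. `INCLUDES` tests closed-interval membership
#' (`low <= value <= high`); `EXCLUDES` is its complement
#' (`value < low` or `value > high`), so the two operators partition the
#' real line for any finite value.
#'
#' @param component_code Component the condition reads.
#' @param operator One of `"EQ"`, `"NE"`, `"INCLUDES"`, `"EXCLUDES"`.
#' @param operand_low,operand_high Interval bounds for
#'   `INCLUDES`/`EXCLUDES` (`operand_low <= operand_high`).
#' @param operand_eq Comparison value for `EQ`/`NE`.
#' @return An object of class `lab_condition`.
#' @export
#' @examples
#' condition("glucose", "INCLUDES", operand_low = 4.0, operand_high = 6.2)
#' condition("hba1c_pct", "EQ", operand_eq = 5.5)
condition <- function(component_code, operator,
                      operand_low = NULL, operand_high = NULL,
                      operand_eq = NULL) {
  structure(list(
    component_code = as.character(component_code),
    operator = as.character(operator),
    operand_low = if (!is.null(operand_low)) as.numeric(operand_low),
    operand_high = if (!is.null(operand_high)) as.numeric(operand_high),
    operand_eq = if (!is.null(operand_eq)) as.numeric(operand_eq)
  ), class = "lab_condition")
}

#' Build condition expressions
#'
#' Rule bodies are finite trees of conditions joined by logical
#' `and`/`or`/`not`, evaluated under Kleene three-valued logic so that a
#' missing observation propagates as UNKNOWN rather than firing or
#' vetoing a rule.
#'
#' @param cond A [condition()] (for `expr_leaf`).
#' @param ... Two or more child expressions (for `expr_and`/`expr_or`).
#' @param expr A single child expression (for `expr_not`).
#' @return An object of class `lab_expr`.
#' @name condition-expressions
#' @export
expr_leaf <- function(cond) {
  structure(list(kind = "LEAF", condition = cond), class = "lab_expr")
}

#' @rdname condition-expressions
#' @export
expr_and <- function(...) {
  structure(list(kind = "AND", children = list(...)), class = "lab_expr")
}

#' @rdname condition-expressions
#' @export
expr_or <- function(...) {
  structure(list(kind = "OR", children = list(...)), class = "lab_expr")
}

#' @rdname condition-expressions
#' @export
expr_not <- function(expr) {
  structure(list(kind = "NOT", children = list(expr)), class = "lab_expr")
}

#' Define a direct inference rule
#'
#' A direct rule emits its artefact when its condition expression
#' evaluates TRUE on the facts of a bundle and no exclusion rule
#' targeting it is effective. Rules follow a 4-eyes lifecycle: they are
#' authored as `DRAFT` and reach `PRODUCTION` only through
#' [promote_rule()] by a reviewer distinct from the author; only
#' `PRODUCTION` rules take part in inference.
#'
#' @param rule_id Identifier.
#' @param test_id Test this rule is scoped to.
#' @param expr A `lab_expr` condition expression.
#' @param artefact_id Artefact emitted when the rule fires unexcluded.
#' @param status One of `"DRAFT"`, `"REVIEWED"`, `"PRODUCTION"`.
#' @param author Authoring expert.
#' @param reviewer Accepting second expert; required (and distinct from
#'   `author`) for `PRODUCTION` status.
#' @return An object of class `lab_direct_rule`.
#' @export
direct_rule <- function(rule_id, test_id, expr, artefact_id,
                        status = "DRAFT", author = "", reviewer = NULL) {
  structure(list(
    rule_id = as.character(rule_id),
    test_id = as.character(test_id),
    expr = expr,
    artefact_id = as.character(artefact_id),
    status = as.character(status),
    author = as.character(author),
    reviewer = if (!is.null(reviewer)) as.character(reviewer)
  ), class = "lab_direct_rule")
}

#' Define an exclusion rule
#'
#' An exclusion rule vetoes one or more direct rules: when its condition
#' expression is TRUE on the same facts, the targeted direct rules emit
#' no artefact even if their own conditions hold.
#'
#' @param exclusion_id Identifier.
#' @param target_rule_ids Non-empty character vector of direct-rule ids.
#' @param expr A `lab_expr` condition expression.
#' @return An object of class `lab_exclusion_rule`.
#' @export
exclusion_rule <- function(exclusion_id, target_rule_ids, expr) {
  structure(list(
    exclusion_id = as.character(exclusion_id),
    target_rule_ids = as.character(target_rule_ids),
    expr = expr
  ), class = "lab_exclusion_rule")
}

#' Define an interpretation artefact
#'
#' Artefacts are the natural-language recommendation blocks added to a
#' patient report when their rule fires. They may carry ICD-10 codes and
#' sensitivity category tags (e.g. `"HIV"`, `"HEPATITIS"`, `"CANCER"`)
#' controlling in-person-only suppression; a non-empty category list
#' requires `sensitive = TRUE`.
#'
#' @param artefact_id Identifier.
#' @param text Non-empty recommendation text. Texts are descriptive, not
#'   prescriptive: they must not assert a single diagnosis as certain.
#' @param icd10_codes Character vector of ICD-10 codes
#'   (letter + digits, optional `.digits`).
#' @param sensitive Logical; TRUE when the result class must be
#'   communicated in person.
#' @param categories Sensitivity category tags.
#' @return An object of class `lab_artefact`.
#' @export
artefact <- function(artefact_id, text, icd10_codes = character(),
                     sensitive = FALSE, categories = character()) {
  structure(list(
    artefact_id = as.character(artefact_id),
    text = as.character(text),
    icd10_codes = as.character(icd10_codes),
    sensitive = isTRUE(sensitive),
    categories = as.character(categories)
  ), class = "lab_artefact")
}

#' Define a test configuration
#'
#' A configuration binds a laboratory test to the ordered list of direct
#' rules evaluated for it; evaluation (and hence artefact and trace
#' order) follows this list.
#'
#' @param test_id Test identifier.
#' @param direct_rule_ids Ordered character vector of rule ids.
#' @return An object of class `lab_test_configuration`.
#' @export
test_configuration <- function(test_id, direct_rule_ids) {
  structure(list(
    test_id = as.character(test_id),
    direct_rule_ids = as.character(direct_rule_ids)
  ), class = "lab_test_configuration")
}

#' Assemble a knowledge base
#'
#' The knowledge base is the versioned container the inference engine
#' runs against: test definitions, per-test configurations, direct and
#' exclusion rules, and artefacts. All cross-references (rule to test,
#' rule to artefact, configuration to rule, exclusion to rule) must
#' resolve; [validate_knowledge_base()] checks every structural
#' invariant and is enforced by [save_knowledge_base()] and
#' [run_inference()].
#'
#' @param version Version string.
#' @param tests List of [lab_test_definition()] objects.
#' @param configurations List of [test_configuration()] objects.
#' @param rules List of [direct_rule()] objects.
#' @param exclusions List of [exclusion_rule()] objects.
#' @param artefacts List of [artefact()] objects.
#' @return An object of class `lab_kb`; maps are named by the contained
#'   identifiers.
#' @export
knowledge_base <- function(version = "1.0", tests = list(),
                           configurations = list(), rules = list(),
                           exclusions = list(), artefacts = list()) {
  name_by <- function(xs, field) {
    xs <- unname(xs)
    stats::setNames(xs, vapply(xs, function(x) x[[field]], character(1)))
  }
  structure(list(
    version = as.character(version),
    tests = name_by(tests, "test_id"),
    configurations = name_by(configurations, "test_id"),
    rules = name_by(rules, "rule_id"),
    exclusions = name_by(exclusions, "exclusion_id"),
    artefacts = name_by(artefacts, "artefact_id")
  ), class = "lab_kb")
}

#' @export
print.lab_kb <- function(x, ...) {
  cat(sprintf(
    "<lab_kb v%s: %d test(s), %d rule(s), %d exclusion(s), %d artefact(s)>\n",
    x$version, length(x$tests), length(x$rules), length(x$exclusions),
    length(x$artefacts)
  ))
  invisible(x)
}
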