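# Order-bundle intake: parse and syntax-check observation bundles arriving
# from a laboratory information system, and resolve component values for
# the inference engine.

#' Construct a patient record
#'
#' @param patient_id Non-empty identifier.
#' @param sex One of `"MALE"`, `"FEMALE"`, `"UNKNOWN"`.
#' @param birth_date Optional ISO-8601 date string.
#' @return An object of class `lab_patient`.
#' @export
patient <- function(patient_id, sex = "UNKNOWN", birth_date = NULL) {
  structure(list(
    patient_id = as.character(patient_id),
    sex = as.character(sex),
    birth_date = if (!is.null(birth_date)) as.character(birth_date)
  ), class = "lab_patient")
}

#' Construct a quantitative observation
#'
#' @param component_code Component measured.
#' @param value Finite decimal value.
#' @param unit Unit string; rules match it verbatim (after whitespace
#'   normalisation), there is no automatic unit conversion.
#' @param observed_at Optional ISO-8601 timestamp; among repeat
#'   measurements of a component the latest timestamp wins.
#' @return An object of class `lab_observation`.
#' @export
observation <- function(component_code, value, unit, observed_at = NULL) {
  structure(list(
    component_code = as.character(component_code),
    value = as.numeric(value),
    unit = as.character(unit),
    observed_at = if (!is.null(observed_at)) as.character(observed_at)
  ), class = "lab_observation")
}

#' Construct an order bundle
#'
#' An order bundle is the set of observations a laboratory information
#' system submits for one patient, grouped by the commercially ordered
#' tests. Repeat measurements of the same component are allowed.
#'
#' @param order_id Non-empty identifier.
#' @param patient A [patient()] object.
#' @param observations List of [observation()] objects.
#' @param ordered_test_ids Character vector of ordered test identifiers.
#' @return An object of class `lab_order_bundle`.
#' @export
order_bundle <- function(order_id, patient, observations = list(),
                         ordered_test_ids = character()) {
  structure(list(
    order_id = as.character(order_id),
    patient = patient,
    observations = unname(observations),
    ordered_test_ids = as.character(ordered_test_ids)
  ), class = "lab_order_bundle")
}

#' @export
print.lab_order_bundle <- function(x, ...) {
  cat(sprintf("<order bundle %s: patient %s, %d observation(s), tests: %s>\n",
              x$order_id, x$patient$patient_id, length(x$observations),
              paste(x$ordered_test_ids, collapse = ", ")))
  invisible(x)
}

#' Parse an order bundle from JSON text
#'
#' Performs the syntax validation applied to incoming data: the document
#' must carry an `order_id`, a `patient` with a non-empty `patient_id`,
#' and observations whose `value` is a finite number and whose `unit` is
#' a string. A bundle with zero observations is valid.
#'
#' @param document JSON text (character scalar) or a parsed list.
#' @return A `lab_order_bundle`.
#' @export
#' @examples
#' parse_order_bundle('{
#'   "order_id": "o1",
#'   "patient": {"patient_id": "p1", "sex": "FEMALE"},
#'   "ordered_test_ids": ["blood_sugar"],
#'   "observations": [
#'     {"component_code": "glucose", "value": 5.1, "unit": "mmol/L"}
#'   ]
#' }')
parse_order_bundle <- function(document) {
  if (is.character(document)) {
    parsed <- tryCatch(
      jsonlite::fromJSON(document, simplifyVector = FALSE),
      error = function(e) {
        stop_labdss(sprintf("malformed order-bundle document: %s",
                            conditionMessage(e)),
                    "labdss_parse_error")
      }
    )
  } else if (is.list(document)) {
    parsed <- document
  } else {
    stop_labdss("order bundle must be JSON text or a parsed list",
                "labdss_parse_error")
  }

  if (is.null(parsed$order_id) || !nzchar(as.character(parsed$order_id))) {
    stop_labdss("order bundle missing non-empty 'order_id'",
                "labdss_schema_error")
  }
  if (is.null(parsed$patient) || is.null(parsed$patient$patient_id) ||
      !nzchar(as.character(parsed$patient$patient_id))) {
    stop_labdss("order bundle missing patient with non-empty 'patient_id'",
                "labdss_schema_error")
  }
  sex <- as.character(parsed$patient$sex %||% "UNKNOWN")
  if (!sex %in% c("MALE", "FEMALE", "UNKNOWN")) {
    stop_labdss(sprintf("patient sex must be MALE/FEMALE/UNKNOWN, got '%s'",
                        sex), "labdss_schema_error")
  }

  obs <- lapply(seq_along(parsed$observations %||% list()), function(i) {
    o <- parsed$observations[[i]]
    code <- as.character(o$component_code %||% "")
    if (!nzchar(code)) {
      stop_labdss(sprintf("observation %d missing component_code", i),
                  "labdss_schema_error")
    }
    v <- o$value
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_labdss(
        sprintf("observation %d ('%s'): value must be a finite number",
                i, code),
        "labdss_value_error"
      )
    }
    if (is.null(o$unit) || !nzchar(as.character(o$unit))) {
      stop_labdss(sprintf("observation %d ('%s') missing unit", i, code),
                  "labdss_schema_error")
    }
    observation(code, v, o$unit, o$observed_at)
  })

  order_bundle(
    order_id = parsed$order_id,
    patient = patient(parsed$patient$patient_id, sex,
                      parsed$patient$birth_date),
    observations = obs,
    ordered_test_ids = unlist(parsed$ordered_test_ids %||% list()) %||%
      character()
  )
}

#' Read an order bundle from a JSON file
#'
#' @param path Path to a bundle JSON file.
#' @return A `lab_order_bundle`.
#' @export
read_order_bundle <- function(path) {
  if (!file.exists(path)) {
    stop_labdss(sprintf("bundle file not found: %s", path),
                "labdss_io_error")
  }
  parse_order_bundle(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

bundle_to_list <- function(bundle) {
  list(
    order_id = bundle$order_id,
    patient = strip_nulls(unclass(bundle$patient)),
    ordered_test_ids = as_json_array(bundle$ordered_test_ids),
    observations = lapply(bundle$observations, function(o) {
      strip_nulls(unclass(o))
    })
  )
}

#' Write an order bundle as a JSON file
#'
#' Uses the same stable dialect as [save_knowledge_base()];
#' `read_order_bundle()` on the output reconstructs an identical bundle.
#'
#' @param bundle A `lab_order_bundle`.
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_order_bundle <- function(bundle, path) {
  write_stable_json(bundle_to_list(bundle), path)
  invisible(path)
}

#' Read a FHIR-flavoured observation bundle
#'
#' Accepts a restricted FHIR-R4-style `Bundle` document holding one
#' `Patient` resource and `Observation` resources with
#' `valueQuantity`, mapping `code.coding[[1]].code` to the component
#' code, `valueQuantity.value`/`unit` to the observation value and unit,
#' and `effectiveDateTime` to the timestamp. FHIR carries no ordered-test
#' list, so `ordered_test_ids` is supplied by the caller.
#'
#' @param path Path to a FHIR-style Bundle JSON file.
#' @param ordered_test_ids Tests the bundle orders.
#' @return A `lab_order_bundle`.
#' @export
read_fhir_bundle <- function(path, ordered_test_ids = character()) {
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(parsed$resourceType, "Bundle")) {
    stop_labdss("document is not a FHIR Bundle", "labdss_schema_error")
  }
  pat <- NULL
  obs <- list()
  for (entry in parsed$entry %||% list()) {
    res <- entry$resource
    if (is.null(res$resourceType)) next
    if (identical(res$resourceType, "Patient")) {
      sex <- switch(tolower(res$gender %||% ""),
                    male = "MALE", female = "FEMALE", "UNKNOWN")
      pat <- patient(res$id %||% "", sex, res$birthDate)
    } else if (identical(res$resourceType, "Observation")) {
      code <- res$code$coding[[1]]$code %||% res$code$text %||% ""
      vq <- res$valueQuantity
      if (is.null(vq)) next
      obs[[length(obs) + 1L]] <- observation(
        code, vq$value, vq$unit %||% "", res$effectiveDateTime
      )
    }
  }
  if (is.null(pat)) {
    stop_labdss("FHIR bundle contains no Patient resource",
                "labdss_schema_error")
  }
  order_bundle(parsed$id %||% "fhir-bundle", pat, obs, ordered_test_ids)
}

#' Match ordered tests against knowledge-base configurations
#'
#' Returns the subset of the bundle's ordered tests for which the
#' knowledge base holds a configuration, preserving order and removing
#' duplicates. Tests without a configuration are silently dropped (the
#' system cannot interpret them).
#'
#' @param kb A `lab_kb`.
#' @param bundle A `lab_order_bundle`.
#' @return Character vector of matched test ids.
#' @export
match_tests <- function(kb, bundle) {
  ids <- unique(bundle$ordered_test_ids)
  ids[ids %in% names(kb$configurations)]
}

normalise_unit <- function(unit) {
  gsub("\\s+", " ", trimws(unit))
}

#' Resolve a component value from a bundle
#'
#' Selects the observation for `component_code` whose unit matches
#' `expected_unit` verbatim (after whitespace normalisation). Among
#' repeat measurements the latest `observed_at` timestamp wins; absent
#' timestamps rank earliest and ties keep the later input position.
#' There is no automatic unit conversion: observations in a different
#' unit are ignored with a warning, and the value resolves to absent
#' (`NA`), which the engine treats as UNKNOWN.
#'
#' @param bundle A `lab_order_bundle`.
#' @param component_code Component to resolve.
#' @param expected_unit Unit the rule/test definition expects.
#' @return A numeric value, or `NA_real_` when no matching observation
#'   exists.
#' @export
resolve_value <- function(bundle, component_code, expected_unit) {
  expected <- normalise_unit(expected_unit)
  same_code <- Filter(
    function(o) identical(o$component_code, component_code),
    bundle$observations
  )
  if (length(same_code) == 0L) return(NA_real_)
  matching <- Filter(function(o) identical(normalise_unit(o$unit), expected),
                     same_code)
  if (length(matching) == 0L) {
    warning(sprintf(
      "component '%s': no observation in expected unit '%s' (found: %s); treating as absent",
      component_code, expected_unit,
      paste(unique(vapply(same_code, function(o) o$unit, character(1))),
            collapse = ", ")
    ), call. = FALSE)
    return(NA_real_)
  }
  stamps <- vapply(matching, function(o) o$observed_at %||% "", character(1))
  best <- which(stamps == max(stamps))
  matching[[best[length(best)]]]$value
}
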