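# Patient-facing report generation: results table with reference-interval
# flags, recommendation blocks, and the in-person-only suppression policy.

#' Define a sensitive-result suppression policy
#'
#' Some result classes must be communicated in person rather than through
#' an automated report: by default positive HIV tests, all kinds of
#' hepatitis, and positive cancer tests. Artefacts tagged with a
#' suppressed category are replaced by a referral notice; the policy
#' never removes the underlying table rows, only the interpretation.
#'
#' @param suppressed_categories Category tags to suppress. An empty
#'   vector disables suppression entirely.
#' @param referral_text Text shown in place of a suppressed artefact.
#' @return An object of class `lab_sensitivity_policy`.
#' @export
sensitivity_policy <- function(
    suppressed_categories = c("HIV", "HEPATITIS", "CANCER"),
    referral_text = paste(
      "A result in this test group requires personal communication.",
      "Please contact the laboratory to discuss it in person with a clinician."
    )) {
  structure(list(
    suppressed_categories = as.character(suppressed_categories),
    mode = "SUPPRESS_WITH_REFERRAL",
    referral_text = as.character(referral_text)
  ), class = "lab_sensitivity_policy")
}

#' Apply a sensitivity policy to an inference result
#'
#' Artefacts whose category tags intersect the policy's suppressed
#' categories are replaced by the policy's referral notice; their text
#' and ICD-10 codes never reach a rendered document. Other artefacts are
#' untouched, and an empty policy is the identity.
#'
#' @param result A `lab_inference_result`.
#' @param policy A [sensitivity_policy()].
#' @return An updated copy of `result`.
#' @export
apply_sensitivity <- function(result, policy = sensitivity_policy()) {
  if (length(policy$suppressed_categories) == 0L) return(result)
  result$artefacts <- lapply(result$artefacts, function(a) {
    if (any(a$artefact$categories %in% policy$suppressed_categories)) {
      a$suppressed <- TRUE
      a$referral_notice <- policy$referral_text
      a$artefact$text <- policy$referral_text
      a$artefact$icd10_codes <- character()
    }
    a
  })
  result
}

flag_value <- function(value, low, high) {
  if (is.null(low) && is.null(high)) return("UNFLAGGED")
  if (!is.null(low) && value < low) return("LOW")
  if (!is.null(high) && value > high) return("HIGH")
  "NORMAL"
}

format_interval <- function(low, high) {
  if (is.null(low) && is.null(high)) return("-")
  sprintf("%s - %s",
          if (is.null(low)) "" else format(low),
          if (is.null(high)) "" else format(high))
}

#' Render the patient results table
#'
#' One row per resolved observation of the bundle's matched tests, in
#' the columns a patient portal shows: parameter name, the result with
#' its unit, and the reference interval, plus a LOW/NORMAL/HIGH flag
#' against that interval (`UNFLAGGED` when the component defines no
#' interval). Components without an observation are omitted.
#'
#' @param kb A `lab_kb`.
#' @param bundle A `lab_order_bundle`.
#' @return A data frame with columns `test_id`, `component_code`,
#'   `parameter`, `value`, `unit`, `reference_low`, `reference_high`,
#'   `reference_interval`, `flag`.
#' @export
render_results_table <- function(kb, bundle) {
  rows <- list()
  for (test_id in match_tests(kb, bundle)) {
    test_def <- kb$tests[[test_id]]
    for (cmp in test_def$components) {
      value <- suppressWarnings(resolve_value(bundle, cmp$code, cmp$unit))
      if (is.na(value)) next
      rows[[length(rows) + 1L]] <- data.frame(
        test_id = test_id,
        component_code = cmp$code,
        parameter = cmp$name,
        value = value,
        unit = cmp$unit,
        reference_low = cmp$reference_low %||% NA_real_,
        reference_high = cmp$reference_high %||% NA_real_,
        reference_interval = format_interval(cmp$reference_low,
                                             cmp$reference_high),
        flag = flag_value(value, cmp$reference_low, cmp$reference_high),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      test_id = character(), component_code = character(),
      parameter = character(), value = numeric(), unit = character(),
      reference_low = numeric(), reference_high = numeric(),
      reference_interval = character(), flag = character(),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Generate a patient report
#'
#' Assembles the full patient-facing document: a patient header, the
#' results table from [render_results_table()], one recommendation block
#' per surviving artefact, and a referral notice for each suppressed
#' one; a result with zero artefacts yields a "no findings" block. The
#' sensitivity policy is applied before rendering, so no suppressed
#' artefact text can appear in the output. Rendering is deterministic:
#' identical inputs produce byte-identical text and HTML.
#'
#' @param kb A `lab_kb`.
#' @param bundle The `lab_order_bundle` the result was computed from.
#' @param result The matching `lab_inference_result`; its `order_id`
#'   must equal the bundle's.
#' @param policy A [sensitivity_policy()].
#' @return An object of class `lab_report_document` with elements
#'   `text` (plain-text lines), `html` (HTML lines), `table` and
#'   `artefacts`.
#' @export
#' @examples
#' fx <- packaged_fixtures()
#' kb <- load_knowledge_base(fx[["blood_sugar_kb"]])
#' bundle <- read_order_bundle(fx[["blood_sugar_bundle"]])
#' doc <- generate_report(kb, bundle, run_inference(kb, bundle))
#' cat(doc$text, sep = "\n")
generate_report <- function(kb, bundle, result,
                            policy = sensitivity_policy()) {
  if (!identical(bundle$order_id, result$order_id)) {
    stop_labdss(sprintf(
      "bundle order_id '%s' does not match result order_id '%s'",
      bundle$order_id, result$order_id
    ), "labdss_consistency_error")
  }
  result <- apply_sensitivity(result, policy)
  tbl <- render_results_table(kb, bundle)

  text <- c(
    "LABORATORY RESULTS REPORT",
    sprintf("Order: %s", bundle$order_id),
    sprintf("Patient: %s", bundle$patient$patient_id),
    "",
    "Results:",
    sprintf("  %-45s %-18s %-15s %s",
            "Parameter name", "My Results", "Reference interval", "Flag")
  )
  if (nrow(tbl) == 0L) {
    text <- c(text, "  (no observations for interpretable tests)")
  } else {
    for (i in seq_len(nrow(tbl))) {
      text <- c(text, sprintf(
        "  %-45s %-18s %-15s %s",
        tbl$parameter[i],
        paste(format(tbl$value[i]), tbl$unit[i]),
        tbl$reference_interval[i], tbl$flag[i]
      ))
    }
  }
  text <- c(text, "", "Interpretation:")
  if (length(result$artefacts) == 0L) {
    text <- c(text, paste(
      "  No findings: the knowledge base found no diagnoses related to",
      "these results."
    ))
  } else {
    for (a in result$artefacts) {
      if (isTRUE(a$suppressed)) {
        text <- c(text, sprintf("  [Referral notice] %s", a$referral_notice))
      } else {
        icd <- if (length(a$artefact$icd10_codes)) {
          sprintf(" (ICD-10: %s)", paste(a$artefact$icd10_codes,
                                         collapse = ", "))
        } else ""
        text <- c(text, sprintf("  - %s%s", a$artefact$text, icd))
      }
    }
  }
  text <- c(text, "", paste(
    "This report is descriptive and informative, not prescriptive.",
    "Please discuss the results with your physician."
  ))

  html <- c(
    "<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
    "<title>Laboratory results report</title></head><body>",
    "<h1>Laboratory results report</h1>",
    sprintf("<p>Order: %s<br/>Patient: %s</p>",
            html_escape(bundle$order_id),
            html_escape(bundle$patient$patient_id)),
    "<table border=\"1\"><tr><th>Parameter name</th><th>My Results</th><th>Reference interval</th><th>Flag</th></tr>"
  )
  if (nrow(tbl) > 0L) {
    for (i in seq_len(nrow(tbl))) {
      html <- c(html, sprintf(
        "<tr><td>%s</td><td>%s %s</td><td>%s</td><td>%s</td></tr>",
        html_escape(tbl$parameter[i]), format(tbl$value[i]),
        html_escape(tbl$unit[i]), html_escape(tbl$reference_interval[i]),
        tbl$flag[i]
      ))
    }
  }
  html <- c(html, "</table>", "<h2>Interpretation</h2>")
  if (length(result$artefacts) == 0L) {
    html <- c(html, "<p>No findings: the knowledge base found no diagnoses related to these results.</p>")
  } else {
    for (a in result$artefacts) {
      if (isTRUE(a$suppressed)) {
        html <- c(html, sprintf("<p><em>Referral notice:</em> %s</p>",
                                html_escape(a$referral_notice)))
      } else {
        icd <- if (length(a$artefact$icd10_codes)) {
          sprintf(" <small>(ICD-10: %s)</small>",
                  html_escape(paste(a$artefact$icd10_codes, collapse = ", ")))
        } else ""
        html <- c(html, sprintf("<p>%s%s</p>",
                                html_escape(a$artefact$text), icd))
      }
    }
  }
  html <- c(html,
            "<p>This report is descriptive and informative, not prescriptive. Please discuss the results with your physician.</p>",
            "</body></html>")

  structure(list(
    order_id = bundle$order_id,
    patient_id = bundle$patient$patient_id,
    table = tbl,
    artefacts = result$artefacts,
    text = text,
    html = html
  ), class = "lab_report_document")
}

#' @export
print.lab_report_document <- function(x, ...) {
  cat(paste(x$text, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a report document to disk
#'
#' @param doc A `lab_report_document`.
#' @param path Destination path; extension `.html` selects the HTML
#'   rendering, anything else the plain-text one.
#' @return Invisibly, `path`.
#' @export
write_report <- function(doc, path) {
  lines <- if (grepl("\\.html?$", path, ignore.case = TRUE)) {
    doc$html
  } else {
    doc$text
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
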