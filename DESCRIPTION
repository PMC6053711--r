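Package: labdss
Title: Rule-Based Decision Support for Patient-Facing Laboratory Result Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A predicate-rule expert system for interpreting quantitative
    laboratory test results for patients. Provides a JSON-serialised
    knowledge base of test definitions, direct inference rules, exclusion
    rules and natural-language recommendation artefacts with ICD-10
    context; a forward-chaining inference engine over three-valued
    (Kleene) condition logic with a complete explanation trace; a report
    generator with reference-interval flagging and a sensitive-result
    suppression policy; and an evaluation battery (classification
    metrics, Cohen's kappa inter-rater agreement, technology-acceptance
    Likert scoring) together with seeded synthetic-data generators for
    order bundles, rater labels and survey responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
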