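# labdss

Rule-based decision support for interpreting laboratory test results for
patients.

In several healthcare systems many patients order laboratory tests
without a physician's referral and then receive bare numbers with no
interpretation. `labdss` implements the decision-support pipeline a
laboratory service can put behind its patient portal: clinical experts
author **direct inference rules** over the atomic components of a
laboratory test; an inference engine evaluates those rules against an
incoming **order bundle** of observations; and a report generator turns
the conclusions into a descriptive, natural-language report with
reference-interval flags and ICD-10 context. The package also ships the
evaluation toolkit used to validate such a system against expert review
and to score patient acceptance.

## The model

A knowledge base holds, per laboratory test, an ordered configuration of
direct rules. A rule's body is a finite expression tree of atomic
conditions over component values, joined by `and` / `or` / `not`. The
comparison operators are

- `=` and `<>` (`EQ` / `NE`), compared within an absolute tolerance of
  1e-9 on decimal values;
- `includes`, closed-interval membership `low <= x <= high`;
- `excludes`, its exact complement `x < low or x > high`.

Expressions evaluate under **Kleene three-valued logic** over
{TRUE, FALSE, UNKNOWN}: a missing observation propagates as UNKNOWN, so
it can neither fire a rule nor veto one (fail-safe on partial bundles).
A direct rule whose expression is TRUE emits its **artefact** — a
natural-language recommendation block, optionally tagged with ICD-10
codes — unless an **exclusion rule** targeting it is also TRUE. Every
evaluated rule is recorded in an explanation trace, so a reviewer can
see exactly how each conclusion was or was not reached.

Rules follow a 4-eyes lifecycle: a rule participates in inference only
in `PRODUCTION` status, which it reaches solely through review and
acceptance by a second expert distinct from its author.

The evaluation battery implements the standard report-quality criteria
(error rate, accuracy, precision `=(all − mistakes)/all`, recall
`=TP/(TP+FN)`, F-measure `=2·P·R/(P+R)`), Cohen's kappa
`κ = (p_o − p_e)/(1 − p_e)` for inter-rater agreement, and mean/median
scoring of a technology-acceptance questionnaire (behavioral intention,
intrinsic motivation, perceived ease of use, perceived usefulness; 1–7
Likert items).

## Worked example

The package ships a blood-sugar knowledge base and a matching order
bundle of five observations (HbA1c in mmol/mol and %, haemoglobin,
plasma glucose, C-peptide):

```r
library(labdss)
fx <- packaged_fixtures()
kb <- load_knowledge_base(fx[["blood_sugar_kb"]])
bundle <- read_order_bundle(fx[["blood_sugar_bundle"]])
res <- run_inference(kb, bundle)
print(res)
#> <inference result for order ord-2024-0001: 1 artefact(s), 5 trace step(s)>
#>   rule 4785 -> artefact 4786
```

The bundle's glucose (7.8 mmol/L) and HbA1c (7 %, 53 mmol/mol) are above
their reference intervals with preserved C-peptide, so the
elevated-glycemia rule `4785` fires, its haemoglobin exclusion rule does
not, and artefact `4786` is emitted. The explanation trace shows each
evaluated rule with the observed values:

```r
explain(res)
#> [DIRECT rule 4785] FIRED
#>     glucose excludes [0, 6.9] | observed: 7.8 | TRUE
#>     hba1c_pct excludes [0, 6.4] | observed: 7 | TRUE
#>     ...
#> [EXCLUSION rule 4795] NOT FIRED - targets rule 4785
#> Conclusion: rule 4785 emitted artefact 4786
```

`generate_report(kb, bundle, res)` renders the patient document: a
results table (`Parameter name / My Results / Reference interval`) with
LOW/NORMAL/HIGH flags — here HbA1c and glucose flag HIGH — followed by
the artefact's recommendation text. Artefacts tagged with a sensitive
category (HIV, hepatitis, cancer by default) are replaced by a referral
notice so such results are only communicated in person.

The evaluation side works from labelled reports and survey tables:

```r
classification_metrics(1000, 7, tp = 993, fn = 7)
#> Reports analysed: 1000, mistakes: 7 (0.7%)
#> Accuracy: 0.99  Precision: 0.99  Recall: 0.99  F-measure: 0.99
proportion(120, 500)
#> [1] 24
```

A thin command-line front end wraps the same functions
(`system.file("cli", "labdss", package = "labdss")`): `labdss kb
validate`, `labdss kb promote`, `labdss infer`, `labdss report`,
`labdss evaluate`, `labdss survey`, `labdss simulate`.

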