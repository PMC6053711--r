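---
title: "Methods: rule-based interpretation of laboratory results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based interpretation of laboratory results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labdss)
```

# The problem and the model

Laboratory services increasingly deliver results directly to patients
who ordered tests without a referral. `labdss` models the automated
interpretation layer for that setting as a first-order-predicate expert
system: experts encode their diagnostic heuristics as rules over the
atomic components of a laboratory test, and the system maps each
incoming set of observations to a list of descriptive recommendation
texts ("located diagnoses") or to a no-findings statement.

The knowledge representation has five moving parts:

* **Test definitions** list a test's components with display name, unit
  and optional reference interval (e.g. plasma glucose, `mmol/L`,
  4.0–6.2). A complete blood count carries 22 such components.
* **Conditions** compare one component's value to operands with `=`,
  `<>`, `includes` and `excludes`.
* **Expressions** join conditions with `and` / `or` / `not` into finite
  trees (`and`/`or` take two or more children, `not` exactly one).
* **Direct rules** bind an expression to exactly one artefact; a
  **configuration** fixes the order in which a test's rules are
  evaluated.
* **Exclusion rules** veto one or more direct rules when their own
  expression holds, letting experts carve exceptions out of a broad
  rule without rewriting it.

## Interval operator semantics

The `includes`/`excludes` glosses in common rule-editor UIs are
ambiguous about boundaries. We fix `includes` as closed-interval
membership (`low <= x <= high`) and `excludes` as its exact complement
(`x < low` or `x > high`): this is the only reading under which the two
operators partition the real line, so an expert can express "normal"
and "abnormal" with the same interval and no gap or overlap at the
boundaries. The test suite asserts this complementarity directly.

## Three-valued evaluation

Real bundles are routinely partial: a rule may reference a component
the patient never had measured. Evaluation therefore runs over Kleene
three-valued logic — a missing value is UNKNOWN, `and` is FALSE-dominant,
`or` is TRUE-dominant, `not` preserves UNKNOWN. Two design decisions
follow:

* a direct rule whose expression is UNKNOWN does **not** fire (no
  recommendation is invented from missing data), and is traced with a
  missing-data annotation;
* an exclusion whose expression is UNKNOWN does **not** veto (a
  confirmed positive finding is not silently discarded because an
  unrelated analyte is missing).

Both choices are fail-safe in the patient-facing direction: absence of
data can only reduce what the system asserts, never add to it. The
equivalence of the recursive evaluator with a truth-table oracle is
checked exhaustively for expressions of up to three leaves.

## Inference procedure

For each ordered test with a configuration in the knowledge base (order
preserved, duplicates dropped), the engine evaluates the configuration's
rules in list order. Only `PRODUCTION` rules participate; drafts are
traced as skipped. When a direct rule is TRUE, all exclusions targeting
it are evaluated; the artefact is emitted only if none is effective.
There is no conflict resolution: every firing, non-excluded rule emits
its artefact, since the intended output is a *list* of candidate
interpretations, not a single diagnosis. Evaluation is single-pass over
observations only — rule chaining (a conclusion feeding another rule's
condition) is noted as a possible extension but deliberately not
implemented, keeping the trace a flat, auditable sequence.

The explanation trace records one step per evaluated rule (direct and
exclusion), each with every leaf condition's description, observed
value and outcome. `explain()` renders it deterministically;
`run_inference()` itself is bit-identical across runs and across
observation reorderings with distinct timestamps.

# Facts and units

Order bundles are minimal JSON documents (schema in
`inst/schemas/order_bundle.schema.json`); a restricted FHIR-R4-style
reader (`read_fhir_bundle()`) maps `Patient` and
`Observation.valueQuantity` resources onto the same structure, since
incoming laboratory feeds are commonly FHIR-shaped.

Two intake rules matter clinically:

* **No unit conversion.** A rule names the unit it expects through the
  test definition; an observation in any other unit resolves to absent
  (UNKNOWN) with a warning. Silent conversion (e.g. mg/dL to mmol/L) is
  a patient-safety hazard we refuse on principle; HbA1c in `%` and in
  `mmol/mol` are therefore distinct components, and rules name which
  they read.
* **Latest observation wins.** Among repeat measurements of a
  component, the latest `observed_at` timestamp is used; missing
  timestamps rank earliest, and exact ties keep the later input
  position. Timestamps compare lexicographically, which is correct for
  ISO-8601 strings in a single timezone — the bundle dialect's stated
  convention.

# Rule lifecycle and the 4-eyes principle

Expert-authored rules are the system's main error source: in production
use, report mistakes trace back to inaccuracies in rule modelling, not
to the engine. The knowledge base therefore enforces a review workflow
structurally: a rule is `DRAFT` when authored, and `promote_rule()` is
the only path to `PRODUCTION` — it requires a reviewer distinct from the
author, records the reviewer, and is idempotent on already-promoted
rules so audit replays cannot corrupt state. Validation independently
rejects any `PRODUCTION` rule whose reviewer is missing or equals its
author, so the invariant holds for hand-edited documents too.

`validate_knowledge_base()` additionally warns (without rejecting) on
*dead rules*: an `includes` interval lying entirely outside the
component's plausible band — the reference interval widened by one
interval width on each side, matching the band the synthetic generator
draws abnormal values from. Such a rule is legal but can never fire on
a plausible value, which usually indicates a typo in the operands.

# Reports and notification ethics

The report document mirrors a patient portal's results view: one row
per resolved observation with parameter name, value and unit, reference
interval and a LOW/NORMAL/HIGH flag (UNFLAGGED when the component
defines no interval; one-sided intervals flag against the available
bound). Artefact texts are descriptive, never prescriptive — the
packaged fixtures phrase every recommendation as "may be consistent
with … discuss with your physician", and the rendered report carries a
standing notice to the same effect.

Result classes that require personal communication (by default the
categories HIV, HEPATITIS and CANCER) are handled by
`apply_sensitivity()`: a matching artefact's text and ICD-10 codes are
replaced by a referral notice before rendering. We chose to show a
notice rather than silently dropping the artefact: the patient learns
that something needs an in-person conversation without the report
disclosing what. Sensitivity is tagged at artefact level (a result
class), not test level, because whole panels are rarely sensitive —
individual positive findings are. An empty category list disables
suppression entirely.

# Evaluation battery

`classification_metrics()` exposes the report-quality criteria exactly
as they are conventionally reported over expert-labelled generated
reports: error rate = mistakes/reports, accuracy = 1 − error rate,
precision = (all − mistakes)/all, recall = TP/(TP+FN), and the
F-measure as the harmonic mean of precision and recall. The precision
form takes whole-report counts; recall needs true-positive and
false-negative counts and is reported as undefined (`NA`) when they are
not supplied or their sum is zero — no confusion matrix is invented
from report counts alone. Display rounding is 2 decimals for these
metrics and 1 decimal for Likert means; stored values are unrounded.

`cohens_kappa()` computes chance-corrected agreement from the raters'
marginals; the degenerate case `p_e = 1` is defined as 1 under perfect
agreement and undefined otherwise. `score_acceptance()` aggregates a
respondent-by-item Likert table (integers 1–7) for the four-criterion
acceptance instrument — behavioral intention (2 items), intrinsic
motivation, perceived ease of use and perceived usefulness (3 items
each) — reporting per-item mean/median/max/min and criterion means as
the mean of item means, with an optional over/under-60 age split.
Consensus settlement between raters is a human step, so labelled-report
inputs carry the consensus label explicitly rather than computing one.

# Synthetic data: what it does and does not emulate

The generators make every module testable without external data, and
their defaults encode the study conditions the evaluation battery is
meant for:

* `generate_bundles()` draws each component value uniformly inside its
  reference interval with probability `1 - abnormal_fraction` (default
  0.3, a plausible abnormal share for a walk-in laboratory population),
  otherwise uniformly in a band extending one interval width beyond a
  randomly chosen bound — abnormal but physiologically plausible.
  Components without a reference interval draw from a documented
  default band `[0, 100]` and are flagged in the output. Alongside each
  bundle the generator records which production rules should fire (net
  of exclusions), computed by a numeric-encoding Kleene evaluator that
  shares no code with the engine; the test suite requires 100%
  generator-vs-engine agreement on the packaged fixtures.
* `generate_rater_labels()` emulates a two-expert review: consensus
  labels are INCORRECT at `error_rate`, and each rater independently
  deviates from consensus at `disagreement_rate / 2`.
* `generate_survey()` draws item responses as
  `1 + Binomial(6, (target − 1)/6)`, whose expectation equals the
  target mean exactly and whose support is the 1–7 Likert range by
  construction.

What the generators do **not** emulate: physiological covariance
between analytes (each value is drawn independently), demographic
structure, panel-specific value distributions, or clinically validated
reference intervals. Passing tests therefore demonstrate the
correctness of the rule machinery and the evaluation arithmetic under
controlled inputs — not the clinical accuracy of any particular rule
set, which in practice is established by expert review of generated
reports.

The packaged blood-sugar fixture deserves the same caveat stated
plainly: its rule thresholds follow common glycemia conventions
(fasting glucose reference 4.0–6.2 mmol/L, impaired fasting glycemia up
to 6.9 mmol/L, HbA1c diabetes thresholds above 6.4 % / 46 mmol/mol) but
are synthetic; only the endpoint identifiers (rule 4785, artefact 4786)
and the five-observation component list are fixed by the worked example
the fixture mirrors. The CBC fixture's 22 component names follow a
standard haematology panel; only the count is externally fixed.

# Numerical and serialisation choices

* `EQ`/`NE` compare within an absolute tolerance of 1e-9 — laboratory
  values are decimals of magnitude roughly 0.1–2000, where 1e-9 is far
  below measurement resolution yet absorbs binary-representation noise.
* Knowledge bases and bundles serialise as UTF-8 JSON with recursively
  sorted keys, 2-space indentation and full-precision numbers, so equal
  objects save byte-identically and `load(save(x))` is the identity;
  `save_knowledge_base()` refuses invalid objects so no persisted
  document can fail to load.
* Identifiers are strings throughout (numeric ids like `4785` are
  accepted and preserved as strings), keeping the format open to
  non-numeric id schemes.
* Degenerate inputs are defined, not crashed on: empty bundles evaluate
  every rule to UNKNOWN and emit nothing; empty rule maps are valid;
  zero denominators in metrics yield `NA` with the printed marker
  "undefined".

# Problem sizes in the test suite

Property-style tests run at sizes chosen to exercise the combinatorics
while keeping the default suite fast: exhaustive Kleene truth tables up
to 3 leaves (3^3 assignments per shape), 1,000 random knowledge-base /
bundle pairs for exclusion monotonicity, 80 random pairs for the
engine-vs-naive-oracle equivalence, 500 random label pairs for the
kappa oracle at 1e-12, and 100 generated bundles for the end-to-end
generator-vs-engine check. The full suite completes in well under a
minute on one CPU.

# Known limitations

* Single-pass inference: no rule chaining, no backward chaining, no
  fuzzy or probabilistic rules.
* No unit conversion, by design; deployments must normalise units
  upstream or define per-unit components.
* Rules are scoped to tests, not to commercial orders; the order level
  exists only as the bundle's `ordered_test_ids`.
* Persistence is flat JSON files plus in-memory objects; there is no
  database layer, concurrent editing or rule version history beyond
  status, author and reviewer.
* The report renderer emits plain text and HTML only; typography (PDF)
  is out of scope.
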