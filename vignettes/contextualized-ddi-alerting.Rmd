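---
title: "Contextualized drug-drug interaction alerting: models, semantics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextualized drug-drug interaction alerting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddialert)
```

## The problem

Conventional drug-drug interaction (DDI) alerting fires whenever two
interacting drugs are co-prescribed, regardless of whether the warning is
relevant to the particular patient. The large majority of such interruptive
alerts are overridden, and the resulting alert fatigue is itself a safety
hazard. `ddialert` implements the alternative: decision-tree algorithms
that, at the moment a basic concomitant exposure is detected, inspect the
patient's record — demographics, recent laboratory values, active and
historical conditions, concomitant drugs, dose, route, visit type — and
classify the event into one of three operational classes:

| Color  | Recommendation                                | Presentation |
|--------|-----------------------------------------------|--------------|
| Red    | Avoid Combination                             | interruptive |
| Yellow | Usually Avoid Combination or Minimize Risk    | interruptive |
| Green  | No Special Precautions                        | filtered     |

Green is the fraction of the conventional alert burden a contextualized
system keeps out of the ordering clinician's workflow; the per-DDI
`filtered_fraction` in a run report is exactly that share.

Eight high-priority DDI algorithms are bundled: citalopram/QT-prolonging
agent, clonidine/beta-blocker, epinephrine/beta-blocker,
fluconazole/opioid, immunosuppressant/fluconazole, potassium/potassium-
sparing diuretic, warfarin/antidepressant and warfarin/salicylate.

## The data model

Populations live in a minimal OMOP-CDM-v5-style `patient_store`: person,
drug_exposure, measurement, condition_occurrence, visit_occurrence, plus a
concept table and a parent-child concept ancestry over RxNorm-, LOINC- and
SNOMED-patterned synthetic vocabularies. Every event time is a timestamp at
minute resolution in UTC; date-only inputs are promoted to midnight. This
matters because the counting rule for duplicate orders — two exposures to
the same drug starting at the *identical timestamp* but with different
free-text dose directions are separate alert events — requires exact
timestamp equality tests, which date/timezone arithmetic would corrupt.

Daily dose is a stored field (`daily_dose_value`/`daily_dose_unit`), not
parsed from the sig: no published sig grammar exists for these algorithms,
so dose tiers operate on whatever the source system recorded. Serum
potassium in mEq/L and mmol/L is treated as numerically identical (a 1:1
equivalence for a monovalent ion).

## Trigger semantics

A *basic concomitant exposure* is one exposure in the algorithm's object
set and one in its precipitant set, same person, with overlapping exposure
periods. Endpoints are inclusive — a shared boundary timestamp counts as
overlap — because that is the alert-retaining reading and the conventional
system being emulated would fire there. The trigger time is the start of
the later-starting exposure, i.e. the order-entry moment at which a CDS
hook would evaluate; ties take the shared start. Pairs are ordered (object,
precipitant) as fixed by each algorithm document and counted once, not
twice; whether a bidirectional count was intended in the original design is
not documented, and the ordered convention keeps counts interpretable as
"alerts at order entry of either drug of a directed pair".

Events outside any visit are retained by default;
`filter_visits_min_duration()` implements the encounter-duration
restriction (inclusive lower bound: a visit of exactly 24 hours satisfies a
24-hour threshold) and can optionally drop events outside retained visits.

## Context extraction

Each tree declares a factor manifest; `build_context()` populates exactly
those factors at the trigger time, with provenance (the source event id)
per factor. Extraction windows are tunable through `context_config()`:

* serum potassium lookback: **3 days** — a potassium value older than an
  inpatient-style 72 hours is not evidence about current kalemia;
* QTc lookback: **30 days** — ECGs are repeated far less often, and a
  month-old QTc is still informative about chronic prolongation;
* withdrawal window: **7 days** — the rebound-hypertension risk window
  after abrupt clonidine discontinuation; the literature does not pin a
  number, so this default is a documented, configurable guess.

One factor needed a design decision the generic operations cannot supply.
"Withdrawal of clonidine" is semantically incompatible with evaluation at
the trigger time, where clonidine is by construction still ongoing. The
bundled tree therefore evaluates the withdrawal factor at the *end of the
object (clonidine) exposure*: it is true when clonidine ends before the
beta-blocker does and no other clonidine exposure is ongoing one minute
after that end — i.e. the patient remains beta-blocked after clonidine
stops. The standalone `detect_discontinuation()` operation keeps the plain
"ended within the window, none ongoing" semantics for use at arbitrary
time points.

### Missing data

MISSING is a first-class factor value (`NA`). Every predicate node declares
which branch a MISSING value takes, and the bundled trees route MISSING
toward the more severe branch: an unmeasured QTc or potassium does not
*exonerate* the patient. In risk-factor counts, a MISSING component counts
as present for the same reason. The consequence is deliberate and worth
stating plainly: under the bundled defaults a patient with no recent labs
cannot reach the most permissive leaves of the citalopram tree. A site that
prefers "no data, no factor" semantics edits the tree documents (they are
data, not code) — for instance flipping `missing_branch` on the QTc node.
The one rule where MISSING is explicitly intermediate is
potassium/potassium-sparing diuretic: a recent K < 5.0 mEq/L is Green, a
recent K ≥ 5.0 is Red, and *no recent value* is Yellow — the absence of a
recent potassium is a reason to warn, but not to claim hyperkalemia.

### Monotonicity

Two trees (citalopram/QT, warfarin/antidepressant) are flagged
`monotone_severity`: adding any declared boolean risk factor, or masking
any known factor to MISSING, can never lower the classification severity
(Red > Yellow > Green). The test suite proves this exhaustively over the
full factor lattice of each flagged tree. The potassium rule is *not*
flagged: its Yellow-on-missing behavior means replacing a known high
potassium with MISSING moves Red to Yellow by design, so the
missing-conservative property cannot and should not hold there.

### Thresholds are reconciliation points

The branch thresholds in the bundled documents — citalopram 40 mg/day,
QTc 480 ms, age 68 and 65, potassium 3.5 and 5.0 mEq/L, fluconazole
200/400 mg/day tiers, oxycodone 40 mg/day, fentanyl 50 mcg/hr,
nonacetylated salicylate 3000 mg/day — are named constants in the tree
JSON, chosen to reproduce the qualitative behavior each algorithm is
documented to have (e.g. the potassium gate mirrors the ≥ 5 mmol/L design
that preceded it). They are defaults to be reconciled against a site's
clinical review, not clinical claims; implementers edit documents only.

### The epinephrine/beta-blocker tree has no Green leaf

The document-based version of that algorithm exempts epinephrine used for
dermatological, dental or plastic-surgery procedures. That branch is not
computable here: the data model (like the CDM it mirrors) does not link a
drug exposure to the condition that indicated it. The computable tree
therefore classifies every co-exposure Yellow or Red, and the test suite
pins both that no Green leaf exists and that every remaining leaf is
reachable.

## Synthetic populations

Three generators, all emitting stores that pass `validate_store()` with
zero violations (a gate in the test suite):

* `generate_validation_population()` — a fixed-census validation population: 93
  persons, 208 drug exposures, 24 lab measurements, 12 condition
  occurrences. For each algorithm it contains one positive scenario (with
  the context events that tree consumes) and one non-overlapping negative
  control, including the duplicate-timestamp citalopram pair that must
  count as two alerts; background persons with non-interacting drugs and
  normal potassium values pad the census to its exact totals. How the
  original validation population was constructed is not documented beyond
  its census, so demographics, dates and the one-positive-one-negative
  structure here are invented; the census and the per-algorithm coverage
  are the fixed points. The population is deterministic — identical for
  every seed — because a validation fixture should not drift.
* `generate_branch_coverage(tree)` — one person per leaf. Root-to-leaf
  paths are enumerated, the factor constraints along each path are solved
  (numeric intervals, boolean/enum requirements, risk-count targets pushed
  down onto components), and record-level events are materialized so each
  extractor reproduces the solved value. The store is self-verified against
  the engine before being returned, and an unsatisfiable leaf raises an
  error naming it — which doubles as a lint for hand-edited trees.
* `generate_random(spec)` — seeded populations for property testing.
  Background exposure/lab/condition/visit counts are Poisson with the
  spec's means; background drugs are drawn only from concepts outside all
  interacting pairs, so the `co_exposure` prevalence alone controls how
  many deliberate overlapping pairs exist (at 0, no algorithm can fire).
  Potassium ~ N(4.3, 0.45) mEq/L and QTc ~ N(435, 30) ms approximate
  plausible inpatient distributions.

What the generators do *not* emulate: longitudinal disease trajectories,
correlated prescribing, realistic visit structure, coding noise, or
vocabulary mapping errors. Passing tests on these populations demonstrates
that the execution semantics are correct, not that the algorithms are
clinically calibrated for any real population.

## Validation by independent recomputation

The permanent regression gate mirrors the practice of validating a rule
engine against independently written database queries:
`oracle_daily_counts()` recomputes per-DDI daily alert counts (basic and
per-color) with exhaustive nested scans over the raw tables, sharing no
helper function with the engine modules — an import-boundary test inspects
the oracle's source to enforce that. Counts are grouped by the UTC
calendar date of the trigger time; "daily" needs a day boundary and
midnight UTC is the store's declared convention. The acceptance suite
requires byte-level agreement on the fixed-census fixture and on 20 seeded
random populations of 200 persons each — sizes chosen to exercise every
algorithm repeatedly while keeping the whole suite comfortably inside a
routine development cycle (the full test run is under two minutes on one
core).

## Known limitations

* The bundled trees use exactly the documented factor vocabulary but
  default branch shapes; sites must reconcile thresholds before any
  clinical use.
* No drug-era construction: exposures are taken as recorded, with no
  persistence-gap merging or taper inference.
* No dose-unit conversion beyond the potassium mEq/L–mmol/L identity; dose
  tiers assume the recorded unit matches the tree's.
* The concept sets are synthetic stand-ins sized to the bundled
  vocabulary; real terminology releases are much larger, and resolution
  cost there is untested.
* Severity is the fixed three-color scheme; no finer risk scoring.
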