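# ddialert

Contextualized drug–drug interaction (DDI) alerting over a minimal
OMOP-CDM-style patient data model.

Most electronic prescribing systems fire a DDI warning whenever two
interacting drugs are co-prescribed. Because the warnings ignore the
patient's actual situation, the overwhelming majority are overridden, and
the resulting alert fatigue is itself a patient-safety problem. `ddialert`
is for informatics teams who want to evaluate the alternative: decision-tree
algorithms that inspect the patient record at the moment of co-exposure and
classify each potential alert as

* **Red** — *Avoid Combination*,
* **Yellow** — *Usually Avoid Combination or Minimize Risk*, or
* **Green** — *No Special Precautions* (the alert a contextualized system
  would keep out of the interruptive workflow).

## What is inside

* A minimal OMOP-style data model (`patient_store`) with CSV readers and
  writers, integrity checking, and an encounter-duration filter.
* Concept sets (RxNorm/LOINC/SNOMED-patterned, with descendant resolution
  over a concept ancestry) shipped as JSON documents.
* A generic decision-tree rule engine: trees are JSON documents — factors,
  predicate nodes with explicit missing-value routing, three-color leaves —
  evaluated against patient context extracted at the trigger time of each
  overlapping co-exposure.
* Eight bundled DDI algorithms: citalopram/QT-prolonging agent,
  clonidine/beta-blocker, epinephrine/beta-blocker, fluconazole/opioid,
  immunosuppressant/fluconazole, potassium/potassium-sparing diuretic,
  warfarin/antidepressant, warfarin/salicylate.
* Synthetic population generators: a fixed-census validation population
  (93 persons, 208 drug exposures, 24 lab measurements, 12 condition
  occurrences, with positive and negative scenarios for every algorithm),
  per-leaf branch-coverage fixtures built by a path-constraint solver, and
  seeded randomized populations.
* An independent brute-force oracle recomputing per-DDI daily alert counts
  for engine/oracle concordance checking, plus a small CLI
  (`inst/cli/ddi-alerts`) with `run`, `simulate`, `validate` and `audit`
  subcommands.

The formal model: each algorithm is a rooted binary decision tree
\(T = (N, \mathrm{root})\) over a factor map \(x\colon F \to V \cup
\{\mathrm{MISSING}\}\); predicate nodes compare \(x(f)\) with a threshold
via one of {<, ≤, >, ≥, =, ∈, present, absent}, MISSING follows the node's
declared branch, and descent terminates at a leaf with color in
{R, Y, G}. A basic concomitant exposure for drug sets \((A, B)\) is a pair
of exposures \((a, b)\) of one person with \([s_a, e_a] \cap [s_b, e_b]
\neq \emptyset\) (inclusive endpoints), triggered at \(\max(s_a, s_b)\).
The per-DDI filtered fraction is \(n_G / n_\mathrm{basic}\).

## Worked example

```r
library(ddialert)

store <- generate_validation_population(1)   # fixed-census validation population
store
#> <patient_store>
#>   person                    93 rows
#>   drug_exposure            208 rows
#>   measurement               24 rows
#>   condition_occurrence      12 rows
#>   visit_occurrence           7 rows
#>   concept                   76 rows
#>   concept_ancestor          46 rows

report <- run_all(store, bundled_trees())
report
#> <ddi_run_report>
#>   ddi_id                            basic   red  yellow  green filtered%
#>   citalopram_qt                         2     2       0      0      0.0%
#>   clonidine_beta_blocker                1     1       0      0      0.0%
#>   epinephrine_beta_blocker              1     1       0      0      0.0%
#>   fluconazole_opioid                    1     0       0      1    100.0%
#>   immunosuppressant_fluconazole         1     1       0      0      0.0%
#>   potassium_k_sparing_diuretic          1     1       0      0      0.0%
#>   warfarin_antidepressant               1     1       0      0      0.0%
#>   warfarin_salicylate                   1     0       1      0      0.0%
#>   TOTAL                                 9     7       1      1     11.1%
```

Reading the table: `basic` is the number of overlapping co-exposures — what
an uncontextualized system would fire as interruptive alerts. The color
columns are the decision-tree classification of each of those events; the
two citalopram alerts come from one patient with two same-timestamp
citalopram orders differing only in dose direction, which are deliberately
counted separately. `filtered%` is the share classified *No Special
Precautions*: here the fluconazole/opioid event (an inpatient on low-dose
fluconazole) is the only one a contextualized system would silence.

Engine-versus-oracle validation on the same store:

```r
engine <- engine_daily_counts(report)
oracle <- do.call(rbind, lapply(bundled_trees(), oracle_daily_counts,
                                store = store))
compare_daily_counts(engine, oracle)
#> <ddi_concordance> concordant: no discrepancies
```

The same operations are scriptable from a shell:

```sh
inst/cli/ddi-alerts simulate --kind replica --out /tmp/pop
inst/cli/ddi-alerts run      --data /tmp/pop --out /tmp/report.json
inst/cli/ddi-alerts validate --data /tmp/pop   # exit 0 iff concordant
inst/cli/ddi-alerts audit
```

## Repository layout

```
R/                   implementation
inst/rules/          the 8 decision-tree documents (JSON; data, not code)
inst/concept_sets/   concept-set documents + per-DDI manifest
inst/config/         default context-extraction configuration
inst/cli/ddi-alerts  command-line entry point
tests/testthat/      unit, property and acceptance tests
vignettes/           methods vignette (model, semantics, validation design)
scripts/acceptance.R census reproduction script
```
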