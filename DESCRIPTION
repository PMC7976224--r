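Package: ddialert
Title: Contextualized Drug-Drug Interaction Alert Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A rule engine for contextualized drug-drug interaction (DDI)
    alerting over a minimal OMOP-CDM-style patient data model. Bundles eight
    decision-tree alert algorithms for high-priority DDIs (citalopram/QT
    prolonging agents, clonidine/beta-blocker, epinephrine/beta-blocker,
    fluconazole/opioid, immunosuppressant/fluconazole, potassium/potassium-
    sparing diuretic, warfarin/antidepressant, warfarin/salicylate) that
    classify each overlapping co-exposure as Red ("Avoid Combination"),
    Yellow ("Usually Avoid Combination or Minimize Risk") or Green ("No
    Special Precautions") from patient context extracted from the record:
    demographics, recent laboratory values, active and historical conditions,
    concomitant drugs, dose, route and visit type. Includes concept-set
    resolution over a terminology ancestry, synthetic population generators
    (a fixed-census validation population, per-leaf branch-coverage fixtures,
    and seeded randomized populations), an independent brute-force oracle for
    daily alert-count concordance checking, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
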