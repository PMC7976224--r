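{
  "ddi_id": "immunosuppressant_fluconazole",
  "name": "Immunosuppressant / fluconazole",
  "object_set": "nti_immunosuppressants",
  "precipitant_set": "fluconazole",
  "monotone_severity": false,
  "risk_factors": [],
  "factors": [
    {
      "name": "flu_topical",
      "type": "boolean",
      "extractor": "drug_route_in",
      "params": {
        "which": "precipitant",
        "set": "fluconazole",
        "routes": ["TOPICAL", "OPHTHALMIC"]
      }
    },
    {
      "name": "flu_dose",
      "type": "numeric",
      "extractor": "daily_dose",
      "params": {
        "which": "precipitant",
        "unit": "mg/day"
      },
      "bounds": [0, 1600]
    },
    {
      "name": "age_years",
      "type": "numeric",
      "extractor": "age",
      "params": [],
      "bounds": [0, 110]
    }
  ],
  "root": "n_topical",
  "nodes": {
    "n_topical": {
      "kind": "predicate",
      "factor": "flu_topical",
      "comparator": "EQ",
      "true_branch": "leaf_green_topical",
      "false_branch": "n_high",
      "missing_branch": "FALSE_BRANCH",
      "threshold": true
    },
    "n_high": {
      "kind": "predicate",
      "factor": "flu_dose",
      "comparator": "GE",
      "true_branch": "leaf_red_high_dose",
      "false_branch": "n_mid",
      "missing_branch": "TRUE_BRANCH",
      "threshold": 400,
      "unit": "mg/day"
    },
    "n_mid": {
      "kind": "predicate",
      "factor": "flu_dose",
      "comparator": "GT",
      "true_branch": "n_age",
      "false_branch": "leaf_green_low_dose",
      "missing_branch": "TRUE_BRANCH",
      "threshold": 100,
      "unit": "mg/day"
    },
    "n_age": {
      "kind": "predicate",
      "factor": "age_years",
      "comparator": "GE",
      "true_branch": "leaf_red_mid_dose_elderly",
      "false_branch": "leaf_yellow_mid_dose",
      "missing_branch": "TRUE_BRANCH",
      "threshold": 65
    },
    "leaf_green_topical": {
      "kind": "leaf",
      "color": "GREEN",
      "recommendation": "No Special Precautions"
    },
    "leaf_red_high_dose": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    },
    "leaf_red_mid_dose_elderly": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    },
    "leaf_yellow_mid_dose": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_green_low_dose": {
      "kind": "leaf",
      "color": "GREEN",
      "recommendation": "No Special Precautions"
    }
  }
}
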