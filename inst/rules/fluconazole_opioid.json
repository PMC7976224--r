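{
  "ddi_id": "fluconazole_opioid",
  "name": "Fluconazole / opioid",
  "object_set": "opioids",
  "precipitant_set": "fluconazole",
  "monotone_severity": false,
  "risk_factors": [],
  "factors": [
    {
      "name": "inpatient",
      "type": "boolean",
      "extractor": "inpatient",
      "params": {
        "min_hours": 24
      }
    },
    {
      "name": "fluconazole_dose",
      "type": "numeric",
      "extractor": "daily_dose",
      "params": {
        "which": "precipitant",
        "unit": "mg/day"
      },
      "bounds": [0, 1600]
    },
    {
      "name": "opioid_kind",
      "type": "enum",
      "extractor": "drug_class",
      "params": {
        "which": "object",
        "classes": [
          {
            "label": "FENTANYL",
            "set": "fentanyl"
          },
          {
            "label": "OXYCODONE",
            "set": "oxycodone"
          }
        ]
      },
      "domain": ["FENTANYL", "OXYCODONE", "OTHER"]
    },
    {
      "name": "opioid_dose",
      "type": "numeric",
      "extractor": "daily_dose",
      "params": {
        "which": "object",
        "unit": "mg/day or mcg/hr"
      },
      "bounds": [0, 400]
    }
  ],
  "root": "n_visit",
  "nodes": {
    "n_visit": {
      "kind": "predicate",
      "factor": "inpatient",
      "comparator": "EQ",
      "true_branch": "n_flu_in",
      "false_branch": "n_flu_out",
      "missing_branch": "FALSE_BRANCH",
      "threshold": true
    },
    "n_flu_in": {
      "kind": "predicate",
      "factor": "fluconazole_dose",
      "comparator": "LE",
      "true_branch": "leaf_green_inpatient_low",
      "false_branch": "n_kind",
      "missing_branch": "FALSE_BRANCH",
      "threshold": 200,
      "unit": "mg/day"
    },
    "n_kind": {
      "kind": "predicate",
      "factor": "opioid_kind",
      "comparator": "EQ",
      "true_branch": "n_fen_dose",
      "false_branch": "n_oxy_dose",
      "missing_branch": "TRUE_BRANCH",
      "threshold": "FENTANYL"
    },
    "n_fen_dose": {
      "kind": "predicate",
      "factor": "opioid_dose",
      "comparator": "GT",
      "true_branch": "leaf_red_fentanyl",
      "false_branch": "leaf_yellow_fentanyl",
      "missing_branch": "TRUE_BRANCH",
      "threshold": 50,
      "unit": "mcg/hr"
    },
    "n_oxy_dose": {
      "kind": "predicate",
      "factor": "opioid_dose",
      "comparator": "GT",
      "true_branch": "leaf_red_oxycodone",
      "false_branch": "leaf_yellow_oxycodone",
      "missing_branch": "TRUE_BRANCH",
      "threshold": 40,
      "unit": "mg/day"
    },
    "n_flu_out": {
      "kind": "predicate",
      "factor": "fluconazole_dose",
      "comparator": "GT",
      "true_branch": "leaf_red_outpatient",
      "false_branch": "leaf_yellow_outpatient",
      "missing_branch": "TRUE_BRANCH",
      "threshold": 200,
      "unit": "mg/day"
    },
    "leaf_green_inpatient_low": {
      "kind": "leaf",
      "color": "GREEN",
      "recommendation": "No Special Precautions"
    },
    "leaf_red_fentanyl": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    },
    "leaf_yellow_fentanyl": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_red_oxycodone": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    },
    "leaf_yellow_oxycodone": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_red_outpatient": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    },
    "leaf_yellow_outpatient": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    }
  }
}
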