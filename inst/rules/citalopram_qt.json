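{
  "ddi_id": "citalopram_qt",
  "name": "Citalopram / QT prolonging agent",
  "object_set": "citalopram",
  "precipitant_set": "qt_prolonging_agents",
  "monotone_severity": true,
  "risk_factors": ["female_sex", "age_ge_68", "loop_diuretic", "hx_mi", "sepsis_dx", "heart_failure_dx"],
  "factors": [
    {
      "name": "female_sex",
      "type": "boolean",
      "extractor": "sex_female",
      "params": []
    },
    {
      "name": "age_ge_68",
      "type": "boolean",
      "extractor": "age_flag",
      "params": {
        "threshold": 68
      }
    },
    {
      "name": "qtc",
      "type": "numeric",
      "extractor": "latest_lab",
      "params": {
        "set": "qtc_lab",
        "unit": "ms"
      },
      "bounds": [300, 700]
    },
    {
      "name": "k_low",
      "type": "boolean",
      "extractor": "lab_flag",
      "params": {
        "set": "serum_potassium_lab",
        "comparator": "LT",
        "threshold": 3.5,
        "unit": "mEq/L"
      }
    },
    {
      "name": "loop_diuretic",
      "type": "boolean",
      "extractor": "concomitant_drug",
      "params": {
        "set": "loop_diuretics"
      }
    },
    {
      "name": "hx_mi",
      "type": "boolean",
      "extractor": "condition",
      "params": {
        "set": "myocardial_infarction",
        "mode": "EVER"
      }
    },
    {
      "name": "sepsis_dx",
      "type": "boolean",
      "extractor": "condition",
      "params": {
        "set": "sepsis",
        "mode": "ACTIVE"
      }
    },
    {
      "name": "heart_failure_dx",
      "type": "boolean",
      "extractor": "condition",
      "params": {
        "set": "heart_failure",
        "mode": "ACTIVE"
      }
    },
    {
      "name": "citalopram_dose",
      "type": "numeric",
      "extractor": "daily_dose",
      "params": {
        "which": "object",
        "unit": "mg/day"
      },
      "bounds": [0, 120]
    },
    {
      "name": "n_risk",
      "type": "numeric",
      "extractor": "risk_count",
      "params": {
        "components": ["female_sex", "age_ge_68", "k_low", "loop_diuretic", "hx_mi", "sepsis_dx", "heart_failure_dx"]
      }
    }
  ],
  "root": "n_qtc",
  "nodes": {
    "n_qtc": {
      "kind": "predicate",
      "factor": "qtc",
      "comparator": "GT",
      "true_branch": "leaf_red_qtc",
      "false_branch": "n_count2",
      "missing_branch": "TRUE_BRANCH",
      "threshold": 480,
      "unit": "ms"
    },
    "n_count2": {
      "kind": "predicate",
      "factor": "n_risk",
      "comparator": "GE",
      "true_branch": "leaf_red_multifactor",
      "false_branch": "n_count1",
      "missing_branch": "TRUE_BRANCH",
      "threshold": 2
    },
    "n_count1": {
      "kind": "predicate",
      "factor": "n_risk",
      "comparator": "GE",
      "true_branch": "leaf_yellow_single_factor",
      "false_branch": "n_dose",
      "missing_branch": "TRUE_BRANCH",
      "threshold": 1
    },
    "n_dose": {
      "kind": "predicate",
      "factor": "citalopram_dose",
      "comparator": "GT",
      "true_branch": "leaf_yellow_high_dose",
      "false_branch": "leaf_green",
      "missing_branch": "TRUE_BRANCH",
      "threshold": 40,
      "unit": "mg/day"
    },
    "leaf_red_qtc": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    },
    "leaf_red_multifactor": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    },
    "leaf_yellow_single_factor": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_yellow_high_dose": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_green": {
      "kind": "leaf",
      "color": "GREEN",
      "recommendation": "No Special Precautions"
    }
  }
}
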