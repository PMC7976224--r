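{
  "ddi_id": "warfarin_antidepressant",
  "name": "Warfarin / antidepressant",
  "object_set": "warfarin",
  "precipitant_set": "antidepressants",
  "monotone_severity": true,
  "risk_factors": ["co_risk", "hx_ugib", "age_ge_65"],
  "factors": [
    {
      "name": "ad_class",
      "type": "enum",
      "extractor": "drug_class",
      "params": {
        "which": "precipitant",
        "classes": [
          {
            "label": "SEROTONERGIC",
            "set": "serotonergic_antidepressants"
          },
          {
            "label": "OTHER_AD",
            "set": "other_antidepressants"
          }
        ]
      },
      "domain": ["SEROTONERGIC", "OTHER_AD", "OTHER"]
    },
    {
      "name": "co_risk",
      "type": "boolean",
      "extractor": "concomitant_drug",
      "params": {
        "set": "warfarin_bleeding_risk_drugs"
      }
    },
    {
      "name": "hx_ugib",
      "type": "boolean",
      "extractor": "condition",
      "params": {
        "set": "ugib_peptic_ulcer",
        "mode": "EVER"
      }
    },
    {
      "name": "age_ge_65",
      "type": "boolean",
      "extractor": "age_flag",
      "params": {
        "threshold": 65
      }
    }
  ],
  "root": "n_class",
  "nodes": {
    "n_class": {
      "kind": "predicate",
      "factor": "ad_class",
      "comparator": "EQ",
      "true_branch": "n_corisk_s",
      "false_branch": "n_corisk_o",
      "missing_branch": "TRUE_BRANCH",
      "threshold": "SEROTONERGIC"
    },
    "n_corisk_s": {
      "kind": "predicate",
      "factor": "co_risk",
      "comparator": "EQ",
      "true_branch": "leaf_red_serotonergic_corisk",
      "false_branch": "n_ugib_s",
      "missing_branch": "TRUE_BRANCH",
      "threshold": true
    },
    "n_ugib_s": {
      "kind": "predicate",
      "factor": "hx_ugib",
      "comparator": "EQ",
      "true_branch": "leaf_red_serotonergic_ugib",
      "false_branch": "n_age_s",
      "missing_branch": "TRUE_BRANCH",
      "threshold": true
    },
    "n_age_s": {
      "kind": "predicate",
      "factor": "age_ge_65",
      "comparator": "EQ",
      "true_branch": "leaf_red_serotonergic_elderly",
      "false_branch": "leaf_yellow_serotonergic",
      "missing_branch": "TRUE_BRANCH",
      "threshold": true
    },
    "n_corisk_o": {
      "kind": "predicate",
      "factor": "co_risk",
      "comparator": "EQ",
      "true_branch": "leaf_yellow_other_corisk",
      "false_branch": "n_ugib_o",
      "missing_branch": "TRUE_BRANCH",
      "threshold": true
    },
    "n_ugib_o": {
      "kind": "predicate",
      "factor": "hx_ugib",
      "comparator": "EQ",
      "true_branch": "leaf_yellow_other_ugib",
      "false_branch": "leaf_green_other",
      "missing_branch": "TRUE_BRANCH",
      "threshold": true
    },
    "leaf_red_serotonergic_corisk": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    },
    "leaf_red_serotonergic_ugib": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    },
    "leaf_red_serotonergic_elderly": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    },
    "leaf_yellow_serotonergic": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_yellow_other_corisk": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_yellow_other_ugib": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_green_other": {
      "kind": "leaf",
      "color": "GREEN",
      "recommendation": "No Special Precautions"
    }
  }
}
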