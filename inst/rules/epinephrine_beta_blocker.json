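{
  "ddi_id": "epinephrine_beta_blocker",
  "name": "Epinephrine / beta-blocker",
  "object_set": "epinephrine",
  "precipitant_set": "beta_blockers",
  "monotone_severity": false,
  "risk_factors": [],
  "comment": "The local/dermatological-indication branch of the document algorithm is omitted: the data model does not link a drug exposure to the condition that indicated it, so that branch is not computable. The computable tree has no GREEN leaf.",
  "factors": [
    {
      "name": "ophthalmic_timolol",
      "type": "boolean",
      "extractor": "drug_route_in",
      "params": {
        "which": "precipitant",
        "set": "timolol",
        "routes": "OPHTHALMIC"
      }
    },
    {
      "name": "bb_class",
      "type": "enum",
      "extractor": "drug_class",
      "params": {
        "which": "precipitant",
        "classes": [
          {
            "label": "ALPHA_BLOCKING",
            "set": "alpha_blocking_beta_blockers"
          },
          {
            "label": "NONSELECTIVE",
            "set": "nonselective_beta_blockers"
          },
          {
            "label": "SELECTIVE",
            "set": "selective_beta_blockers"
          }
        ]
      },
      "domain": ["ALPHA_BLOCKING", "NONSELECTIVE", "SELECTIVE", "OTHER"]
    },
    {
      "name": "anaphylaxis_hx",
      "type": "boolean",
      "extractor": "condition",
      "params": {
        "set": "anaphylaxis",
        "mode": "EVER"
      }
    },
    {
      "name": "epi_dose",
      "type": "numeric",
      "extractor": "daily_dose",
      "params": {
        "which": "object",
        "unit": "mg/day"
      },
      "bounds": [0, 10]
    },
    {
      "name": "epi_route",
      "type": "enum",
      "extractor": "drug_route",
      "params": {
        "which": "object"
      },
      "domain": ["ORAL", "IV", "TOPICAL", "OPHTHALMIC", "TRANSDERMAL", "LOCAL_INJECTION", "OTHER"]
    }
  ],
  "root": "n_ophth",
  "nodes": {
    "n_ophth": {
      "kind": "predicate",
      "factor": "ophthalmic_timolol",
      "comparator": "EQ",
      "true_branch": "leaf_yellow_ophthalmic",
      "false_branch": "n_class",
      "missing_branch": "FALSE_BRANCH",
      "threshold": true
    },
    "n_class": {
      "kind": "predicate",
      "factor": "bb_class",
      "comparator": "EQ",
      "true_branch": "n_ana",
      "false_branch": "n_route",
      "missing_branch": "TRUE_BRANCH",
      "threshold": "NONSELECTIVE"
    },
    "n_ana": {
      "kind": "predicate",
      "factor": "anaphylaxis_hx",
      "comparator": "EQ",
      "true_branch": "leaf_red_anaphylaxis",
      "false_branch": "n_dose",
      "missing_branch": "TRUE_BRANCH",
      "threshold": true
    },
    "n_dose": {
      "kind": "predicate",
      "factor": "epi_dose",
      "comparator": "GT",
      "true_branch": "leaf_red_high_dose",
      "false_branch": "leaf_yellow_nonselective",
      "missing_branch": "TRUE_BRANCH",
      "threshold": 0.5,
      "unit": "mg/day"
    },
    "n_route": {
      "kind": "predicate",
      "factor": "epi_route",
      "comparator": "EQ",
      "true_branch": "leaf_yellow_iv",
      "false_branch": "leaf_yellow_other",
      "missing_branch": "TRUE_BRANCH",
      "threshold": "IV"
    },
    "leaf_yellow_ophthalmic": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_red_anaphylaxis": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    },
    "leaf_red_high_dose": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    },
    "leaf_yellow_nonselective": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_yellow_iv": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_yellow_other": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    }
  }
}
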