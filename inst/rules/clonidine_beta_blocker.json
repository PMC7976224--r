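{
  "ddi_id": "clonidine_beta_blocker",
  "name": "Clonidine / beta-blocker",
  "object_set": "clonidine",
  "precipitant_set": "beta_blockers",
  "monotone_severity": false,
  "risk_factors": [],
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
      "name": "clonidine_withdrawal",
      "type": "boolean",
      "extractor": "withdrawal",
      "params": {
        "set": "clonidine",
        "window_days": 7
      }
    }
  ],
  "root": "n_ophth",
  "nodes": {
    "n_ophth": {
      "kind": "predicate",
      "factor": "ophthalmic_timolol",
      "comparator": "EQ",
      "true_branch": "leaf_green_ophthalmic",
      "false_branch": "n_alpha",
      "missing_branch": "FALSE_BRANCH",
      "threshold": true
    },
    "n_alpha": {
      "kind": "predicate",
      "factor": "bb_class",
      "comparator": "EQ",
      "true_branch": "leaf_green_alpha",
      "false_branch": "n_nonsel",
      "missing_branch": "FALSE_BRANCH",
      "threshold": "ALPHA_BLOCKING"
    },
    "n_nonsel": {
      "kind": "predicate",
      "factor": "bb_class",
      "comparator": "EQ",
      "true_branch": "n_withdrawal",
      "false_branch": "leaf_yellow_selective",
      "missing_branch": "TRUE_BRANCH",
      "threshold": "NONSELECTIVE"
    },
    "n_withdrawal": {
      "kind": "predicate",
      "factor": "clonidine_withdrawal",
      "comparator": "EQ",
      "true_branch": "leaf_red_withdrawal",
      "false_branch": "leaf_yellow_nonselective",
      "missing_branch": "TRUE_BRANCH",
      "threshold": true
    },
    "leaf_green_ophthalmic": {
      "kind": "leaf",
      "color": "GREEN",
      "recommendation": "No Special Precautions"
    },
    "leaf_green_alpha": {
      "kind": "leaf",
      "color": "GREEN",
      "recommendation": "No Special Precautions"
    },
    "leaf_yellow_selective": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_red_withdrawal": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    },
    "leaf_yellow_nonselective": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    }
  }
}
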