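{
  "ddi_id": "potassium_k_sparing_diuretic",
  "name": "Potassium / potassium-sparing diuretic",
  "object_set": "potassium_supplements",
  "precipitant_set": "k_sparing_diuretics",
  "monotone_severity": false,
  "risk_factors": [],
  "comment": "Alerting restricted to a recent serum potassium of 5.0 mEq/L or more; a recent normal value is classified No Special Precautions and no recent value at all keeps a noninterruptive warning.",
  "factors": [
    {
      "name": "serum_potassium",
      "type": "numeric",
      "extractor": "latest_lab",
      "params": {
        "set": "serum_potassium_lab",
        "unit": "mEq/L"
      },
      "bounds": [1, 9]
    }
  ],
  "root": "n_present",
  "nodes": {
    "n_present": {
      "kind": "predicate",
      "factor": "serum_potassium",
      "comparator": "PRESENT",
      "true_branch": "n_k",
      "false_branch": "leaf_yellow_no_recent_k",
      "missing_branch": "TRUE_BRANCH"
    },
    "n_k": {
      "kind": "predicate",
      "factor": "serum_potassium",
      "comparator": "GE",
      "true_branch": "leaf_red_hyperkalemia",
      "false_branch": "leaf_green_normal_k",
      "missing_branch": "TRUE_BRANCH",
      "threshold": 5,
      "unit": "mEq/L"
    },
    "leaf_yellow_no_recent_k": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_red_hyperkalemia": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    },
    "leaf_green_normal_k": {
      "kind": "leaf",
      "color": "GREEN",
      "recommendation": "No Special Precautions"
    }
  }
}
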