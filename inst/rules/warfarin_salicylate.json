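{
  "ddi_id": "warfarin_salicylate",
  "name": "Warfarin / salicylate",
  "object_set": "warfarin",
  "precipitant_set": "salicylates",
  "monotone_severity": false,
  "risk_factors": [],
  "factors": [
    {
      "name": "topical_salicylate",
      "type": "boolean",
      "extractor": "drug_route_in",
      "params": {
        "which": "precipitant",
        "set": "topical_salicylates",
        "routes": "TOPICAL"
      }
    },
    {
      "name": "sal_class",
      "type": "enum",
      "extractor": "drug_class",
      "params": {
        "which": "precipitant",
        "classes": [
          {
            "label": "NONACETYLATED",
            "set": "nonacetylated_salicylates"
          },
          {
            "label": "ASPIRIN",
            "set": "aspirin"
          }
        ]
      },
      "domain": ["NONACETYLATED", "ASPIRIN", "OTHER"]
    },
    {
      "name": "nonacet_dose",
      "type": "numeric",
      "extractor": "daily_dose",
      "params": {
        "which": "precipitant",
        "unit": "mg/day"
      },
      "bounds": [0, 6000]
    },
    {
      "name": "thromboembolic_ind",
      "type": "boolean",
      "extractor": "condition",
      "params": {
        "set": "thromboembolic_conditions",
        "mode": "ACTIVE"
      }
    }
  ],
  "root": "n_topical",
  "nodes": {
    "n_topical": {
      "kind": "predicate",
      "factor": "topical_salicylate",
      "comparator": "EQ",
      "true_branch": "leaf_green_topical",
      "false_branch": "n_class",
      "missing_branch": "FALSE_BRANCH",
      "threshold": true
    },
    "n_class": {
      "kind": "predicate",
      "factor": "sal_class",
      "comparator": "EQ",
      "true_branch": "n_dose",
      "false_branch": "n_ind",
      "missing_branch": "FALSE_BRANCH",
      "threshold": "NONACETYLATED"
    },
    "n_dose": {
      "kind": "predicate",
      "factor": "nonacet_dose",
      "comparator": "GT",
      "true_branch": "leaf_yellow_nonacetylated_high",
      "false_branch": "leaf_green_nonacetylated_low",
      "missing_branch": "TRUE_BRANCH",
      "threshold": 3000,
      "unit": "mg/day"
    },
    "n_ind": {
      "kind": "predicate",
      "factor": "thromboembolic_ind",
      "comparator": "EQ",
      "true_branch": "leaf_yellow_aspirin_indicated",
      "false_branch": "leaf_red_aspirin",
      "missing_branch": "FALSE_BRANCH",
      "threshold": true
    },
    "leaf_green_topical": {
      "kind": "leaf",
      "color": "GREEN",
      "recommendation": "No Special Precautions"
    },
    "leaf_yellow_nonacetylated_high": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_green_nonacetylated_low": {
      "kind": "leaf",
      "color": "GREEN",
      "recommendation": "No Special Precautions"
    },
    "leaf_yellow_aspirin_indicated": {
      "kind": "leaf",
      "color": "YELLOW",
      "recommendation": "Usually Avoid Combination or Minimize Risk"
    },
    "leaf_red_aspirin": {
      "kind": "leaf",
      "color": "RED",
      "recommendation": "Avoid Combination"
    }
  }
}
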