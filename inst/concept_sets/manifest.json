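{
  "schema": "Each concept-set document is a JSON object with fields: set_id (string), name (string), vocabulary (RXNORM|LOINC|SNOMED), seed_concept_ids (non-empty integer array), include_descendants (boolean), excluded_concept_ids (integer array). Membership = seeds plus transitive descendants (when include_descendants) minus exclusions.",
  "sets_by_ddi": {
    "citalopram_qt": ["citalopram", "qt_prolonging_agents", "qtc_lab", "serum_potassium_lab", "loop_diuretics", "myocardial_infarction", "sepsis", "heart_failure"],
    "clonidine_beta_blocker": ["clonidine", "beta_blockers", "timolol", "alpha_blocking_beta_blockers", "nonselective_beta_blockers", "selective_beta_blockers"],
    "epinephrine_beta_blocker": ["epinephrine", "beta_blockers", "timolol", "alpha_blocking_beta_blockers", "nonselective_beta_blockers", "selective_beta_blockers", "anaphylaxis"],
    "fluconazole_opioid": ["opioids", "fluconazole", "fentanyl", "oxycodone"],
    "immunosuppressant_fluconazole": ["nti_immunosuppressants", "fluconazole"],
    "potassium_k_sparing_diuretic": ["potassium_supplements", "k_sparing_diuretics", "serum_potassium_lab"],
    "warfarin_antidepressant": ["warfarin", "antidepressants", "serotonergic_antidepressants", "other_antidepressants", "warfarin_bleeding_risk_drugs", "ugib_peptic_ulcer"],
    "warfarin_salicylate": ["warfarin", "salicylates", "nonacetylated_salicylates", "aspirin", "topical_salicylates", "thromboembolic_conditions"]
  }
}
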