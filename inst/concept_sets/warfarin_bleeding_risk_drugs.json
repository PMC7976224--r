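{
  "set_id": "warfarin_bleeding_risk_drugs",
  "name": "bleeding-risk co-medication (NSAID, aspirin, systemic corticosteroid, aldosterone antagonist, antiplatelet)",
  "vocabulary": "RXNORM",
  "seed_concept_ids": [1170, 1180, 1190, 1111, 1114, 1200],
  "include_descendants": true,
  "excluded_concept_ids": []
}
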