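{
  "lookback_days": {
    "serum_potassium_lab": 3,
    "qtc_lab": 30
  },
  "default_lookback_days": 30,
  "withdrawal_window_days": 7,
  "unit_equivalences": {
    "serum_potassium": ["mEq/L", "mmol/L"]
  }
}
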