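{
  "max_goal": 15000,
  "confidence_band": [70, 90],
  "increment": 500,
  "rounding": 100,
  "floor": 2000,
  "raise_threshold_days": 4,
  "hold_range_days": [2, 3]
}
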