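{
  "version": 1,
  "n": 2000,
  "prevalence": {"anxiety": 0.35, "depression": 0.35, "stress": 0.25},
  "severity_present": {"shape1": 4, "shape2": 2},
  "severity_absent": {"shape1": 2, "shape2": 5},
  "loading_range": [0.7, 1.0],
  "sigma_obs": 4,
  "jitter_prob": 0.05,
  "cross_attenuation": 0.6,
  "seed": 20260101,
  "note": "Synthetic cohort parameters; all data produced from these are simulated, not collected."
}
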