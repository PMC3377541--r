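{
  "variable_name": "pct_below_15",
  "units": "% of time",
  "mu": 32.5,
  "var_bs": 152.8,
  "var_bd": 65.6,
  "var_wd": 616.1,
  "acf_targets": {"1": 0.51, "2": 0.33, "3": 0.26, "4": 0.22, "5": 0.18, "10": 0.09},
  "clip_bounds": null,
  "day_length": 480,
  "bias_adjust": true
}
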