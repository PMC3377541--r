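{
  "variable_name": "pct_above_90",
  "units": "% of time",
  "mu": 4.7,
  "var_bs": 3.0,
  "var_bd": 4.0,
  "var_wd": 164.7,
  "acf_targets": {"1": 0.52, "2": 0.34, "3": 0.26, "4": 0.22, "5": 0.17, "10": 0.08},
  "clip_bounds": null,
  "day_length": 480,
  "bias_adjust": true
}
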