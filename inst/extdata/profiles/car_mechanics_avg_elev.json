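{
  "variable_name": "avg_elevation",
  "units": "degrees",
  "mu": 29.2,
  "var_bs": 22.2,
  "var_bd": 9.2,
  "var_wd": 234.9,
  "acf_targets": {"1": 0.55, "2": 0.37, "3": 0.29, "4": 0.23, "5": 0.19, "10": 0.09},
  "clip_bounds": null,
  "day_length": 480,
  "bias_adjust": true
}
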