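{
  "kind": "speckle",
  "seed": 11,
  "x_range_m": [-0.0065, 0.0065],
  "z_range_m": [0.018, 0.032],
  "density_per_cell": 12,
  "mean_amp": 1
}
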