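{
  "geometry": {
    "n_elements": 128,
    "pitch_m": 3e-04,
    "f0_hz": 5e+06,
    "fs_hz": 2e+07,
    "c_m_per_s": 1540
  },
  "grid": {
    "x_min_m": -0.006,
    "x_max_m": 0.006,
    "z_min_m": 0.02,
    "z_max_m": 0.032
  },
  "therapy": {
    "treat_window_s": 0.05,
    "prf_hz": 3000,
    "therapy_cycles": 160,
    "vis_cycles": 2,
    "imaging_cycles": 3,
    "imaging_taper": "hann",
    "image_window_s": 2,
    "n_pwc_angles": 11,
    "max_angle_deg": 18,
    "frames_per_image_window": 1
  },
  "transmits": [
    {"kind": "focused", "focus_x_m": 0, "focus_z_m": 0.025},
    {"kind": "planewave", "angle_deg": 0}
  ],
  "noise_sd": 0,
  "seed": 1
}
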