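{
  "body_major_axis": 11,
  "body_minor_axis": 3.5,
  "flagellum_length": 13,
  "flagellum_radius": 0.25,
  "beat_amplitude": 1.8,
  "beat_wavelength": 13,
  "beat_frequency": 28,
  "beat_direction": "puller",
  "body_scale": 1,
  "gamma_d": 1,
  "geometry": "bulk_shear",
  "mu": 8.9e-4,
  "wall_present": false,
  "repulsion_enabled": false,
  "repulsion_g": 1250,
  "repulsion_l": 0.2,
  "dt_per_beat": 100,
  "n_phases": 20,
  "n_theta": 36,
  "refinement": 1,
  "seed": 1
}
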