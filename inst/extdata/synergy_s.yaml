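machine:
  sad_cm: 100.0
  source_to_mlc_cm: 39.0
  leaf_thickness_cm: 7.5
  leaf_width_iso_cm: 0.4
  max_field_x_cm: 16.0
  max_field_y_cm: 21.0
  min_gap_iso_cm: 0.2564
model:
  tip_radius_cm: 13.0
  offset_shift_cm: 0.1
  offset_table: default
energies:
- label: 6MV
  full_leaf_transmission: 0.02
  reference_dose_cgy: 131.9
  scatter_fraction: 0.08
  kernel_sigma_cm: 0.35
- label: 10MV
  full_leaf_transmission: 0.025
  reference_dose_cgy: 145.0
  scatter_fraction: 0.08
  kernel_sigma_cm: 0.35
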