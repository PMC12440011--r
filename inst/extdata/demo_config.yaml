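seed: 20240901
experiment:
  conditions:
  - 11mM
  - 33mM
  control: 11mM
  intact_multiplier:
    11mM: 1.0
    33mM: 0.333333333333333
  detached_multiplier:
    11mM: 1.0
    33mM: 2.0
  n_organoids_per_condition: 8.0
  organoid_loss_fraction:
    '3': 0.15
    '6': 0.3
image:
  well_size_px:
  - 160.0
  - 160.0
  body_radius_px:
  - 16.0
  - 20.0
  detached_cell_count: 6.0
  detached_cell_radius_px:
  - 2.0
  - 3.0
  detached_ring_px:
  - 4.0
  - 24.0
  background_mean: 20.0
  noise_sd: 6.0
segmentation:
  threshold_offset: 50.0
  connectivity: 8.0
  min_object_px: 4.0
  main_body_min_px: 150.0
  ratio_epsilon_px: 1.0
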