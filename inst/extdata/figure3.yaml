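# Insulin-gradient model sweep: pancreas volume vs beta-cell density for
# pure single-size cluster populations at full (100%) acinar expansion.
figure_id: figure3
calibration:
  baseline_volume: 60
  reference_volume: 90
  density_max: 0.03
cell_radius: 5
model:
  type: gradient
  extents: [1, 5, 10, 20, 30]
  truncation_multiple: 5
expansion: [1.0]
clusters:
  sizes: [1, 5, 25, 100, 250, 500, 1000]
density_grid:
  from: 0
  to: 0.03
  by: 0.001
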