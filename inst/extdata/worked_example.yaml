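# Overlap worked example: a single beta cell vs a 100-cell cluster under a
# 20 um constant shell at full expansion, evaluated at the density extremes.
figure_id: worked_example
calibration:
  baseline_volume: 60
  reference_volume: 90
  density_max: 0.03
cell_radius: 5
model:
  type: shell
  extents: [20]
expansion: [1.0]
clusters:
  sizes: [1, 100]
density_grid:
  values: [0, 0.015, 0.03]
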