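# Expansion-magnitude sweep over the heterogeneous islet-size distribution,
# both action models, expansions 20% / 50% / 100%.
figure_id: figure4
calibration:
  baseline_volume: 60
  reference_volume: 90
  density_max: 0.03
cell_radius: 5
model:
  type: both
  extents: [1, 5, 10, 20, 30]
  truncation_multiple: 5
expansion: [0.2, 0.5, 1.0]
clusters:
  distribution:
    id: autopsy_mixed
    sizes: [1, 10, 25, 100, 250, 1000]
    weights: [0.05, 0.10, 0.20, 0.40, 0.20, 0.05]
density_grid:
  from: 0
  to: 0.03
  by: 0.001
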