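# Example synthetic scenario: 12 smooth, mildly cross-correlated layers on
# a 60 x 60 grid; niche-shaped suitability driven by env01..env03;
# 150 presences.
grid_shape: [60, 60]
n_layers: 12
smoothness: 3
cross_correlation: 0.3
true_variables: [env01, env02, env03]
true_coefficients:
  linear: [2, -2, 2]
  quadratic: [-2, -2, -2]
n_presences: 150
nodata_fraction: 0.02
seed: 42
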