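# Example screening configuration. Defaults mirror the package's standard
# ensemble design: 100 sprints of 10 runs, random k-variable subsets,
# top-6 selection, LQHP features with regularization multiplier 1.0.
k_per_run: 6
runs_per_sprint: 10
n_sprints: 100
top_k: 6
master_seed: 1
checkpoints: [25, 50, 100]
settings:
  feature_classes: LQHP
  regularization_multiplier: 1.0
  hinge_knots: 50
  threshold_knots: 50
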