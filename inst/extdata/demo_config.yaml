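# Demo run: small synthetic corpus, build + align + 2-tier LR evaluation.
seed: 42
out_dir: qoe_run
stages: [simulate, build, align, evaluate]
simulate:
  n_reviews: 60
  corrupt_fraction: 0.1
build:
  k: 5
align:
  max_distance: 3
evaluate:
  task: grade2
  model: lr
  variant: nct
  trials: 2
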