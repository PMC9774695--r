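# Example pipeline configuration: simulate a herd, clean it, and run the
# repeated 3-fold cross-validation over all six scenarios.
simulate:
  enabled: true
  n_cows: 120
association: slope
mcmc:
  chains: 2
  burnin: 1500
  iter: 1500
evaluation:
  folds: 3
  repeats: 3
  v: [60, 150, 240]
  threshold: 0.5
  n_draws: 500
  obs_thin: 3
seeds:
  simulation: 101
  partition: 102
  mcmc: 103
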