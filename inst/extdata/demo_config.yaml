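# Reduced demo run: one synthetic cohort, small forest, scaled-down
# reshuffling null.  All sizes are demo-scale; see vignette for the
# full-analysis defaults.
seed: 7
sim:
  n_respondents: 1000
forest:
  n_trees: 50
  alpha_split: 1
  min_node_size: 20
pipeline:
  folds: 5
  repetitions: 2
  n_reshuffles: 200
sensitivity:
  age_grouping: tertiles
  exposures: [duration, multiplicity, severity]
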