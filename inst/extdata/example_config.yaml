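# Example run configuration for stocktactics::read_run_config().
mode: synthetic
seed: 1
n_trees: 2000
mtry: 5
min_node_size: 5
scenario: key
fleet:
  n_stocks: 85
  process_sd: 0.10
  implementation_sd: 0.15
  assessment_sd: 0.15
  discard_base: 0.15
  f_target_mult: 0.75
  b_target_frac: 0.40
  final_year: 2010
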