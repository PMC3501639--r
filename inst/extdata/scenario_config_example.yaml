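# Example override file for enumerate_scenarios(); values merge over
# default_scenario_config(). The shipped defaults are reconstructions of
# plausible bowhead demographic parameters and are meant to be replaced
# where better estimates exist.
census:
  BCB: 16000
  HBFB: 680
migration_rates: [0.1, 0.01, 0.001]
ancestral_merge_gen: 2000
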