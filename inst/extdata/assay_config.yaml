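markers:
  sim_snp:
    allele1_window:
    - 50.0
    - 57.0
    allele2_window:
    - 57.5
    - 64.0
sg_window: 17
sg_order: 3
dae_threshold_percent: 20.0
alpha: 0.05
ci_level: 0.95
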