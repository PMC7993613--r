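{
  "n_f2": 52,
  "pool_sizes": {"mut": 12, "wt": 40},
  "chrom_length_bp": 25000000,
  "recomb_rate": 1e-08,
  "n_snps": 125000,
  "causal_pos": 12500000,
  "misphenotype_prob": 0.142857142857143,
  "coverage": {"mut": 37.6, "wt": 36.5},
  "base_error": 0.001,
  "seed": 1
}
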