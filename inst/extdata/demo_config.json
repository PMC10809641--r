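{
  "seed": 20260101,
  "simulate": {
    "n_subjects": 120,
    "n_cpgs": 1200,
    "n_lmrs": 40,
    "lmr_cpg_range": [5, 10],
    "n_signal_features": 40,
    "effect_size": 0.005,
    "progression_sd": 5,
    "expression": {"n_genes": 300, "n_effect_genes": 30, "effect_r": 0.5},
    "n_gene_sets": 10,
    "gene_set_size": 20
  },
  "lmr": {"n_shuffles": 5},
  "clock": {"k": 10, "n_lambda": 100},
  "enrichment": {"n_perm": 500, "min_sources": 2}
}
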