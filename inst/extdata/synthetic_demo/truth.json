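{
  "n_samples": 12,
  "n_taxa": 40,
  "regime": "mixed",
  "m": 0.3,
  "sigma_w": 0.5,
  "N": 2000,
  "depth": 1000,
  "generations": 100,
  "lognormal_sigma": 1,
  "sigma2_bm": 1,
  "trait_root": 25,
  "env_jitter_sd": 0.5,
  "seed": 20,
  "regime_per_sample": ["mixed", "mixed", "mixed", "mixed", "mixed", "mixed", "mixed", "mixed", "mixed", "mixed", "mixed", "mixed"]
}
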