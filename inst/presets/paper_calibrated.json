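{
  "n_nuclear_genes": 6000,
  "n_plastid_genes": 80,
  "n_mito_genes": 120,
  "n_spike_species": 92,
  "class_proportions": {
    "plastid": 0.1,
    "mitochondrion": 0.06,
    "dual": 0.02,
    "other": 0.62,
    "unknown": 0.2
  },
  "tier_proportions": {
    "none": 0.787,
    "complexed": 0.177,
    "direct": 0.036
  },
  "rate_meanlog": {
    "nuclear": 1,
    "plastid": -2.4,
    "mitochondrion": -2.8
  },
  "rate_sdlog": {
    "nuclear": 1.2,
    "plastid": 1,
    "mitochondrion": 1
  },
  "length_meanlog": 0.4,
  "length_sdlog": 0.6,
  "ploidy_levels": ["2C", "4C"],
  "reps_per_ploidy": 3,
  "organ": "sepal",
  "organelle_copies_2c": {
    "plastid": 500,
    "mitochondrion": 50
  },
  "organelle_genome_response": {
    "plastid": 0.76,
    "mitochondrion": 1.01
  },
  "dosage_multiplier": {
    "plastid": 0.85,
    "mitochondrion": 1.05,
    "dual": 0.95,
    "other": 1.1,
    "unknown": 1.1
  },
  "ratio_sd": {
    "other": 0.55,
    "unknown": 0.55,
    "none": 0.4,
    "complexed": 0.25,
    "direct": 0.02
  },
  "tier_coupling": {
    "none": 0.3,
    "complexed": 0.6,
    "direct": 0.9
  },
  "org_ratio_sd": 0.05,
  "coordination_mode": {
    "plastid": "coordinated",
    "mitochondrion": "boosted"
  },
  "mito_boost": 1.5,
  "dispersion": 0.05,
  "depth": 5000000,
  "spike_fraction": 0.02,
  "spike_meanlog": 0,
  "spike_sdlog": 2,
  "rna_per_dna_2c": 10,
  "qpcr_noise_sd": 0.05,
  "qpcr_efficiency": 2,
  "complexes": {
    "RUBISCO": {
      "nuclear": 4,
      "plastid": 1
    },
    "PSII": {
      "nuclear": 8,
      "plastid": 4
    },
    "OXPHOS_III": {
      "nuclear": 9,
      "mitochondrion": 1
    },
    "OXPHOS_II": {
      "nuclear": 4
    }
  },
  "seed": 1
}
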