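{
  "title": "invanet pipeline report",
  "required": {
    "seed": "number",
    "parameters": "any",
    "design": {
      "required": {
        "n_samples": "number",
        "n_sites": "number",
        "n_otus": "number",
        "n_assays": "number"
      }
    },
    "qmec": {
      "required": {
        "detected_fraction": "number",
        "detected_genes_per_category": "any"
      }
    },
    "community": {
      "required": {
        "alpha": "any",
        "anosim": {
          "required": {
            "statistic": "number",
            "p_value": "number",
            "n_permutations": "number"
          }
        },
        "proportion_explained": "number",
        "kw_phylum": "any",
        "kw_family": "any"
      }
    },
    "network": "any",
    "drivers": "any",
    "spatial": "any"
  }
}
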