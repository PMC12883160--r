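{
  "seed": 101,
  "stages": ["expression", "sv", "idmap"],
  "params": {
    "alpha": 0.05,
    "cv_max": 0.1,
    "eps": 0.01,
    "lfc_min": 2,
    "max_distance": 1000,
    "padj_max": 0.01,
    "promoter_bp": 2000,
    "tau_min": 0.85
  },
  "genome": {
    "n_chrom": 5,
    "genome_bp": 10000000,
    "n_genes": 2000,
    "partition": {
      "exon": 0.1801065,
      "intron": 0.1191677,
      "intergenic": 0.7007258
    }
  },
  "expression": {
    "n_samples": 54,
    "n_expressed_anywhere": 1989,
    "n_expressed_everywhere": 1038,
    "n_never_expressed": 11,
    "n_ts_called": 97,
    "ts_sensitivity": 0.95,
    "ts_fdp": 0.0206185567,
    "n_hk_called": 106,
    "hk_sensitivity": 1,
    "hk_tau_max": 0.1178700321,
    "tissue_ari": 1
  },
  "sv": {
    "n_input_calls": 636,
    "n_merged": 260,
    "n_tier1": 149,
    "n_tier2": 37,
    "n_tier3": 74,
    "n_high_confidence": 186,
    "tier_match_truth": true,
    "te_background_p": 0.3012874,
    "te_categories": {
      "TE_depleted": 58,
      "TE_derived_complex": 33,
      "TE_derived_occupancy": 37,
      "background": 19
    },
    "enrichment": {
      "observed": {
        "exon": 41727,
        "intron": 37112,
        "intergenic": 119122
      },
      "statistic": 11552.31424,
      "df": 2,
      "p_value": 0
    },
    "n_sv_genes": 184,
    "association": {
      "expression_p": 1.609275759e-08,
      "expression_direction": "SV_lower",
      "tau_p": 3.124090149e-05,
      "lfc_p": 6.705932472e-85,
      "by_region": {
        "exon": {
          "n": 2,
          "p_adj": 0.01961739944
        },
        "promoter": {
          "n": 103,
          "p_adj": 0.001928869926
        },
        "spanning": {
          "n": 79,
          "p_adj": 4.888387736e-06
        }
      }
    }
  },
  "idmap": {
    "n_genes": 2000,
    "confidence_counts": {
      "orthogroup_1to1": 200,
      "orthogroup_best": 150,
      "synteny_1to1": 1500,
      "unmapped": 150
    },
    "accuracy": 1
  }
}
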