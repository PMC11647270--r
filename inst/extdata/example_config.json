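{
  "seed": 1,
  "n_genes": 300,
  "n_cell_types": 3,
  "p_de": 0.1,
  "logfc_magnitude": 1,
  "n_cells_per_type": 600,
  "n_spots": 150,
  "array_rows": 25,
  "array_cols": 25,
  "uniformity_prob": 0.7,
  "density_high_rate": 4,
  "density_low_rate": 0.5,
  "density_high_prob": 0.5,
  "leakage": {"bleed_rate": 0.3, "kernel_sd": 2},
  "downsample": {"pct": 0.05, "accurate": false},
  "deg": {"alpha": 0.01, "input_mode": "containing"},
  "specificity": {"metric": "mean", "threshold": 0.3}
}
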