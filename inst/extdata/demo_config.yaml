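# Demo run: bundled 14-population plaque preset with a candidate set
# planted into the endothelial populations.
master_seed: 42
outdir: plaqmap_demo
simulate:
  enabled: true
  preset: plaque
  n_cells: 3282
  n_genes: 2000
  n_markers: 15
  marker_fold: 4
candidates:
  target: [EC9, EC10]
  n_candidates: 30
  enrich_frac: 0.4
degs:
  alpha: 0.05
  lfc_min: 0.25
  min_cells: 3
patterns:
  k: 15
  restarts: 50
  z_annot: 1.0
enrich:
  n_perm: 5000
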