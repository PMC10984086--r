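# Demo configuration: a small but complete end-to-end run.
seed: 1
stages: [simulate, chrometrics, classify, spatial, signatures]
tissue:
  gc_radius: 300
  n_b_cells: 900
  t_intensity: 5.0e-4
  dz_t_retention: 0.2
nuclei:
  n_dz: 60
  n_lz: 60
expression:
  n_genes: 600
  n_de: 60
classifier:
  k: 5
  n_trees: 200
spatial:
  n_perm: 199
  band_width: 100
  bin_width: 10
  pixel_size: 4
signatures:
  alpha: 0.05
  min_datasets: 3
  n_cohorts: 4
  es_n_perm: 199
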