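# Example pipeline configuration: simulate a small sharing-mode realm and
# run every stage. Override `outdir` and `seed` as needed;
# run_pipeline("this_file.yaml") fills unspecified keys with defaults.
outdir: results/toy_run
seed: 7
simulate: true
grid:
  lon_min: -10
  lon_max: 10
  lat_min: -10
  lat_max: 10
  resolution: 1
world:
  n_hosts: 60
  n_parasites: 30
  mode: sharing
  sharing_coefs: [2.0, -6.0]
  sharing_distance: trait
  range_median_cells: 25
richness:
  aicc: false
  signal_variant: "K*"
  n_perm: 499
sharing:
  min_hosts: 6
  n_iter: 200
  replace: true
pca:
  min_variance: 0.75
buffer_km: 100
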