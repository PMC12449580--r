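# Small end-to-end demonstration configuration: synthetic data with a known
# band-topology association graph, two hosts' worth of planted structure,
# reduced replication and a short StARS path so the whole run stays fast.
seed: 42
simulate:
  n_features: 40
  topology: band
  density: 0.05
  n_replicates: 4
  n_core: 4
  n_host_specific: 2
  depth_mean: 5000
  effect_size: 1.0
filter:
  min_depth: 100
core:
  min_reads: 3
  min_prevalence: 0.9
  min_abundance_fraction: 1.0e-5
stats:
  factor: substrate
  n_perm: 199
  pairwise: true
network:
  groups:
    - "F_serratus|seaweed"
    - "F_serratus|proxy_biofilm"
    - "G_vermiculophylla|seaweed"
  level: wmc
  min_total_reads: 3
  min_mean_rel_abund: 0.0025
  n_lambda: 15
  n_subsamples: 10
  beta_threshold: 0.05
  rule: or
metrics:
  z_thresh: 2.5
  p_thresh: 0.62
  n_restarts: 5
netcompare:
  standardize: zscore
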