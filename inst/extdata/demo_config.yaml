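# Demo pipeline configuration: a small synthetic study of all four
# modalities. Keys mirror the arguments of pipeline_config().
seed: 1
design:
  n_genes: 1000
  n_replicates: 3
  frac_up: 0.05
  frac_down: 0.05
  effect_log2fc: 2
  nb_dispersion: 0.05
thresholds:
  background_rpkm: 0.1
  log2fc_min: 1
  fdr_max: 0.10
protocol:
  dc_levels: [-150, -110, -70, -30, 10, 50, 90]
noise_rms_pA: 5
stages: [expression, nlc, stiffness, cytology]
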