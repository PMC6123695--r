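# Example experiment configuration for fmrirep_cli().
# Fields mirror experiment_config(); tasks are synthetic dataset specs.
seed: 1
n_sorts: 20
k_grid: [16, 36, 64]
n_null_maps: 100
metrics: [pearson, jaccard_voxel, jaccard_cluster, peak_hit]
tasks:
  - name: demo_low_bv
    share_group: demo
    n_subjects: 200
    n_runs: 2
    sigma_between: 0.3
    sigma_within: 1.0
    noise_fwhm: 3
    grid_shape: [24, 24, 24]
    blobs:
      - {center: [8, 8, 12], fwhm: 4, amplitude: 1.0, sign: 1}
      - {center: [16, 16, 12], fwhm: 4, amplitude: 0.8, sign: 1}
      - {center: [16, 8, 16], fwhm: 4, amplitude: 0.8, sign: -1}
  - name: demo_high_bv
    share_group: demo
    n_subjects: 200
    n_runs: 2
    sigma_between: 0.8
    sigma_within: 1.0
    noise_fwhm: 3
    grid_shape: [24, 24, 24]
    blobs:
      - {center: [8, 8, 12], fwhm: 4, amplitude: 1.0, sign: 1}
      - {center: [16, 16, 12], fwhm: 4, amplitude: 0.8, sign: 1}
      - {center: [16, 8, 16], fwhm: 4, amplitude: 0.8, sign: -1}
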