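# Example pipeline configuration: four PEG-PCL-PE polyurethane blends
# emulated synthetically from the bundled reference coefficients (hydrated,
# body temperature), then fitted and swept over the default frequency and
# geometry grids.
seed: 42
temperature_K: 310.15
strain_unit: fraction
waveform:
  p_max: 180    # mmHg
  p_min: 40     # mmHg
  ps: 10        # mmHg
omega_grid: [1.0, 1.5, 2.0]   # Hz
r0_grid: [1.5, 2.0, 3.0]      # mm
h_grid: [0.3, 0.4, 0.5]       # mm
samples_per_cycle: 256
n_cycles: 3
n_grid: 200
materials:
  - label: "5-90-5"
    synthetic:
      c10: 0.589
      c01: -0.416
      c11: -0.0399
      lambda_max: 2.5
      n_points: 100
      n_replicates: 5
      noise_sd: 0.02
      replicate_jitter_cv: 0.05
  - label: "45-45-10"
    synthetic:
      c10: -1.41
      c01: 3.03
      c11: 0.223
      lambda_max: 2.5
      n_points: 100
      n_replicates: 5
      noise_sd: 0.02
      replicate_jitter_cv: 0.05
  - label: "46.3-46.3-7.5"
    synthetic:
      c10: -0.854
      c01: 1.82
      c11: 0.132
      lambda_max: 2.5
      n_points: 100
      n_replicates: 5
      noise_sd: 0.02
      replicate_jitter_cv: 0.05
  - label: "47.5-47.5-5"
    synthetic:
      c10: -0.812
      c01: 1.66
      c11: 0.101
      lambda_max: 2.5
      n_points: 100
      n_replicates: 5
      noise_sd: 0.02
      replicate_jitter_cv: 0.05
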