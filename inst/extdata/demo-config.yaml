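# Demonstration run: small synthetic cohort, full pipeline.
seed: 1
out_dir: scanpathr-demo
geometry:
  width_px: 1920
  height_px: 1080
  distance_mm: 855
  calib_deg: 5.0
  calib_px: 270
synthetic:
  n_participants: 6
  n_trials: 6
  n_fixations: 25
  n_anchors: 8
  encoding_coupling: 0.7
preprocess:
  min_ms: 100
  max_ms: 5000
rqa:
  radius_deg: 2.5
  l_min: 2
similarity:
  amp_threshold_frac: 0.10
  dir_threshold_deg: 45
  dur_threshold_ms: 300
contrasts:
  - measure: recurrence_rate
    a: MI
    b: FP
  - measure: determinism
    a: MI
    b: FP
  - measure: laminarity
    a: MI
    b: FP
n_boot: 1000
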