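geometry:
  n_elements: 80
  pitch_um: 270.0
  virtual_source_depth_mm: 21.6
  sound_speed: 1540.0
  f_tx_mhz: 2.4
  f_center_mhz: 2.84
  prf: 5490.0
  steering_angles_deg:
  - -15.0
  - -3.0
  - 9.0
  - 15.0
  - 3.0
  - -9.0
  n_am_pulses: 3
  imaging_depth_mm: 120.0
simulation:
  phantom: branching
  centre_mm:
  - 0.0
  - 70.0
  length_mm: 14.0
  diameter_um: 300.0
  duration_s: 5.0
  bubble_rate: 20.0
  snr_db: 30.0
  motion:
    enabled: yes
    period_s: 0.8
    peak_um: 1500.0
  seed: 1
processing:
  gating: yes
  svd_fraction: 0.05
  bspline_spacing: 32
  tp_lambda: 0.01
  sr_um: 13.5
  ncc_threshold: 0.5
  max_speed_mm_s: 150.0
  min_track_frames: 4
  seed: 1
output:
  dir: srulm_run
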