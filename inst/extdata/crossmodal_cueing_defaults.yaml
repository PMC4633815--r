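n_subjects: 28.0
invert_lsw: yes
threshold_p: 0.05
n_permutations: 3000.0
alpha: 0.05
seed: 1.0
n_channels: 128.0
design:
  p_nocue: 0.333333333333333
  p_valid_given_cued: 0.75
  block_size: 9
  n_blocks: 10
  durations_ms:
  - 66.0
  - 100.0
  - 133.0
  per_block_duration_balance: yes
  counterbalance_arm: soundA_faces
  familiarization_trials: 10
  allocation: exact
  forward_mask_ms: 1000.0
  cue_onset_after_mask_onset_ms: 500.0
  cue_duration_ms: 250.0
  backward_mask_total_ms: 1800.0
  interblock_interval_ms: 1500.0
  feedback_duration_ms: 3000.0
kernel:
  p1_center_ms: 240.0
  p1_sigma_ms: 25.0
  p1_base_uv: 6.0
  p1_valid_offset_uv: 3.0
  p400_center_ms: 450.0
  p400_sigma_ms: 40.0
  p400_base_uv: 5.0
  p400_face_offset_uv: 2.0
  p400_cued_offset_uv: 2.0
  lsw_center_ms: 1070.0
  lsw_sigma_ms: 90.0
  lsw_base_uv: -5.0
  lsw_face_offset_uv: -2.0
  lsw_invalid_offset_uv: -3.0
  spatial_sigma: 0.6
  subject_sd_uv: 1.0
noise:
  noise_rms_uv: 10.0
  noise_exponent: 1.0
  p_artifact: 0.25
  p_large_given_artifact: 0.25
  small_channels:
  - 2
  - 12
  large_channels:
  - 48
  - 90
  small_amp_uv:
  - 150.0
  - 390.0
  large_amp_uv:
  - 420.0
  - 700.0
  p_lookaway: 0.246666666666667
preproc:
  srate_hz: 250.0
  hp_hz: 0.2
  lp_hz: 20.0
  epoch_window_ms:
  - -150.0
  - 1700.0
  abs_voltage_reject_uv: 400.0
  local_deviation_uv: 400.0
  local_deviation_window_samples: 10
  bad_channel_trial_fraction: 0.35
  smoothing_threshold_uv: 120.0
  smoothing_window_samples: 5
  interp_k: 4
  baseline_window_ms:
  - -150.0
  - 0.0
  min_trials_per_condition: 2
roi:
- TP9
- P9
- PO7
- O1
- OZ
- O2
- PO8
- P10
- TP10
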