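optics:
  parallax_angle_deg: 28.1
  fov_x_um: 110.0
  fov_y_um: 110.0
  dof_um: 100.0
  frame_w_px: 512
  frame_h_px: 512
  volume_rate_hz: 30.0
restoration:
  cutoff: 0.3
  rl_iterations: 10
  psf_sigma_um: 0.4
detection:
  mode: hough
  r_min_px: 7.0
  r_max_px: 14.0
  sensitivity: 0.85
  block_size_px: 31
  blob_radius_px: 2.0
matching:
  weights:
  - 0.5
  - 0.25
  - 0.25
  row_tol_px: 2.0
tracking:
  max_link_dist_um: 5.0
  max_gap_frames: 2
  max_gap_dist_um: 7.0
  z_weight: 1.0
  min_length: 3
seed: 1
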