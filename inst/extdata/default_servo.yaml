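control_period: 0.0111111
camera_period: 0.0333333
latency_frames: 1.0
noise_pos_sd: 0.0
max_speed: 500.0
max_accel: 400.0
marker_count: 4.0
marker_radius: 15.0
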