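wbscan 1
unit_id: 7
label: hand-built synthetic fixture
timestamp: 2026-01-02T03:04:05Z
pan_start: 0
pan_stop: 64
pan_step_size: 64
tilt_start: 0
tilt_stop: 64
tilt_step_size: 64
max_integration: 2000000
min_integration: 500
dark_interval: 1
steps_per_revolution: 2048
gear_ratio_pan: 1
gear_ratio_tilt: 1
n_rows: 2
n_cols: 2
n_channels: 4
n_photosites: 4
compression_window: 1
saturation_level: 65535
wl_coeffs: 400,100,0,0,0,0
lin_a: 1
lin_b: 0
end_header
D 3 500 10 11 12 13
D 6 1000 20 21 22 23
P 1 1 M 0 1 500 110 211 312 413
P 1 2 M 0 2 500 1010 2011 3012 4013
P 2 1 M 0 4 1000 520 1021 1522 2023
P 2 2 I 0 4 1000 270 521 772 1023
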