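farm_id: H1
n_cows: 70
barn_area: 625
n_cubicles: 66
n_water_troughs: 2
n_ams: 1
n_cameras: 3
camera_height: 4.9
camera_spacing: 14.5
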