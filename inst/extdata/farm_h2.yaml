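farm_id: H2
n_cows: 140
barn_area: 1225
n_cubicles: 132
n_water_troughs: 5
n_ams: 2
n_cameras: 8
camera_height: 5.7
camera_spacing: 13.4
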