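farm_id: H3
n_cows: 250
barn_area: 1820
n_cubicles: 218
n_water_troughs: 8
n_ams: 5
n_cameras: 14
camera_height: 6.0
camera_spacing: 13.8
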