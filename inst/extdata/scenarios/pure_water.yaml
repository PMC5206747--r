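label: pure_water
treatment: crude
droplet_volume_ml: 0.01
n_plates: 5
droplets_per_plate: 47
min_temp_c: -25.0
classes: []
background:
  temp_mean_c: -16.2
  temp_sd_c: 0.5
  max_temp_c: -10.0
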