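label: paper_like_rain
treatment: crude
droplet_volume_ml: 0.01
n_plates: 5
droplets_per_plate: 47
min_temp_c: -25.0
classes:
- label: biological_cells
  concentration_per_ml: 7.4
  temp_mean_c: -5.5
  temp_sd_c: 1.2
  heat_sensitive: yes
  size_nm: 1000.0
- label: submicron_resistant
  concentration_per_ml: 105.0
  temp_mean_c: -8.8
  temp_sd_c: 1.9
  heat_sensitive: no
  size_nm: 110.0
background:
  temp_mean_c: -16.0
  temp_sd_c: 0.8
  max_temp_c: -10.0
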