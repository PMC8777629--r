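{"temperature_K":297.15,"complete_shift_hz":-25,"chamber_volume_mm3":58,"sensor_area_mm2":97,"sauerbrey_constant_ng_per_cm2_per_hz":17.7,"exchange_factor":0.05,"lipid":"DOPC","truth":{"mu_diff_true":585,"noise_sd":1,"seed":42}}
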