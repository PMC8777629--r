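{
  "chamber_volume_mm3": 58,
  "sensor_area_mm2": 97,
  "sauerbrey_constant_ng_per_cm2_per_hz": 17.7,
  "exchange_factor": 0.05
}
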