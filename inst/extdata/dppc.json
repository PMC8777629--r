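{
  "name": "DPPC",
  "molecular_weight_g_per_mol": 734.039,
  "transition_temperature_K": 314,
  "apl_gel_A2": 47.5,
  "apl_fluid_A2": 61.3,
  "apl_slope_gel_A2_per_K": 0.06,
  "apl_slope_fluid_A2_per_K": 0.2
}
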