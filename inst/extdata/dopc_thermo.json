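{
  "mu_diff_J_per_mol": 585,
  "temperature_K": 297.15,
  "substrate": "hydrophilic"
}
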