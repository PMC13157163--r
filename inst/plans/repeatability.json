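{
  "_comment": "Trajectory-repeatability (power-analysis) design: one environment, 10 repeated trials per strategy; feed the 45 trajectory pairs to power_analysis().",
  "n_environments": 1,
  "repeats": 10,
  "sweep": "none",
  "n_corals": 25,
  "seed": 42
}
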