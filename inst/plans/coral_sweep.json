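{
  "_comment": "Desk-scale environment-complexity sweep over coral counts.",
  "n_environments": 5,
  "repeats": 1,
  "sweep": "corals",
  "sweep_values": [5, 10, 20, 30, 40],
  "seed": 42
}
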