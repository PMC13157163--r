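{
  "_comment": "Desk-scale arena-size sweep; coral count and duration scale with the side length.",
  "n_environments": 5,
  "repeats": 1,
  "sweep": "arena",
  "sweep_values": [2, 4, 6, 8, 10],
  "seed": 42
}
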