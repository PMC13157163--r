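{
  "_comment": "Desk-scale positional-noise sweep.",
  "n_environments": 5,
  "repeats": 1,
  "sweep": "noise",
  "sweep_values": [0, 0.1, 0.3],
  "seed": 42
}
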