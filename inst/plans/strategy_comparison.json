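{
  "_comment": "Desk-scale strategy comparison: 20 environments, one trial each. Run: fishnav sweep --plan strategy_comparison.json --strategies hp,azimuth,null --pop-scale 0.2 --out results/",
  "n_environments": 20,
  "repeats": 1,
  "sweep": "none",
  "n_corals": 25,
  "seed": 42
}
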