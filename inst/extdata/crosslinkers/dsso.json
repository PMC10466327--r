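{
  "name": "DSSO",
  "comment": "Disuccinimidyl sulfoxide, CID-cleavable. Stubs: A = alkene, T = unsaturated thiol, S = sulfenic acid. Only A+S reconstitute the spacer; T is the water-loss partner of S.",
  "spacer": {"C": 6, "H": 6, "O": 3, "S": 1},
  "stubs": {
    "A": {"C": 3, "H": 2, "O": 1},
    "T": {"C": 3, "H": 2, "O": 1, "S": 1},
    "S": {"C": 3, "H": 4, "O": 2, "S": 1}
  },
  "doublet_pair": ["A", "T"],
  "hydrogen_shifts": [0],
  "complementary_pairs": [["A", "S"]]
}
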