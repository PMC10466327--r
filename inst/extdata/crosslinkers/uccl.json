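{
  "name": "UCCL",
  "comment": "UVPD-cleavable benzyl-mercaptan crosslinker. Stub compositions are structure-derived (symmetric thioether spacer with a xylylene core), not taken from a printed table; edit here if corrected values become available.",
  "spacer": {"C": 12, "H": 12, "O": 2, "S": 2},
  "stubs": {
    "A": {"C": 2, "H": 2, "O": 1},
    "B": {"C": 2, "H": 2, "O": 1, "S": 1},
    "C": {"C": 10, "H": 10, "O": 1, "S": 1},
    "D": {"C": 10, "H": 10, "O": 1, "S": 2}
  },
  "doublet_pair": ["B", "C"],
  "hydrogen_shifts": [-2, -1, 0, 1, 2],
  "complementary_pairs": [["A", "D"], ["B", "C"]]
}
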