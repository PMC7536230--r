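{
  "version": 1,
  "constants": {
    "gamma": 0.0067,
    "b": 2,
    "mu": 0.00026,
    "n_circuit_copies": 9,
    "n_output_copies": 4,
    "output_promoter": "BM3R1",
    "sensor_on":  {"Tac": 0.045, "Tet1": 1.537, "Tet2": 0.982, "BAD1": 0.043, "BAD2": 0.054},
    "sensor_off": {"Tac": 0.0000018, "Tet1": 0.0000266, "Tet2": 0.0000018, "BAD1": 0.0000018, "BAD2": 0.0000037}
  },
  "topology": {
    "genes": ["phlF", "srpR", "bm3R1", "betI", "ameR", "hlyIIR", "amtR", "yfp"],
    "inputs": {
      "phlF": ["SrpR", "BetI"],
      "srpR": ["BAD1", "Tet1"],
      "bm3R1": ["PhlF", "HlyIIR"],
      "betI": ["AmtR", "AmeR"],
      "ameR": ["Tet2"],
      "hlyIIR": ["Tac"],
      "amtR": ["BAD2"],
      "yfp": ["BM3R1"]
    },
    "gate_of_promoter": {"PhlF": "phlF", "SrpR": "srpR", "BM3R1": "bm3R1", "BetI": "betI", "AmeR": "ameR", "HlyIIR": "hlyIIR", "AmtR": "amtR"},
    "sensors": ["Tac", "Tet1", "Tet2", "BAD1", "BAD2"],
    "sensor_of_inducer": {"IPTG": ["Tac"], "aTc": ["Tet1", "Tet2"], "Ara": ["BAD1", "BAD2"]},
    "readthrough": {
      "srpR": {"from": "phlF", "terminator": "T37"},
      "bm3R1": {"from": "srpR", "terminator": "T00"},
      "betI": {"from": "bm3R1", "terminator": "T2P11"},
      "ameR": {"from": "betI", "terminator": "T3P11"},
      "hlyIIR": {"from": "ameR", "terminator": "T31"},
      "amtR": {"from": "hlyIIR", "terminator": "T36"}
    },
    "gene_parts": {
      "phlF":   {"ribozyme": "riboJ53", "rbs": "P3", "terminator": "ECK120033737", "terminator_label": "T37"},
      "srpR":   {"ribozyme": "riboJ10", "rbs": "S2", "terminator": "ECK120029600", "terminator_label": "T00"},
      "bm3R1":  {"ribozyme": "sarJ", "rbs": "B2", "terminator": "L3S2P11", "terminator_label": "T2P11"},
      "betI":   {"ribozyme": "riboJ57", "rbs": "E1", "terminator": "L3S3P11", "terminator_label": "T3P11"},
      "ameR":   {"ribozyme": "riboJ54", "rbs": "F1", "terminator": "L3S3P31", "terminator_label": "T31"},
      "hlyIIR": {"ribozyme": "riboJ51", "rbs": "H1", "terminator": "ECK120033736", "terminator_label": "T36"},
      "amtR":   {"ribozyme": "bydvJ", "rbs": "A1", "terminator": "L3S2P21", "terminator_label": "T21"},
      "yfp":    {"ribozyme": "riboJ", "rbs": "BBa_B0064", "terminator": "L3S2P55", "terminator_label": "T55"}
    }
  }
}
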