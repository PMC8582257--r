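{
  "id": "oxazole",
  "name": "oxazole",
  "description": "Planar five-membered aromatic ring (1,3-oxazole); semi-experimental fit excluded the D4/D5 isotopologues and used predicates for C4-H4, C5-H5, HCN and CCH.",
  "levels": ["SE", "revDSD", "PW6B95"],
  "atoms": [["O1", "O"], ["C2", "C"], ["N3", "N"], ["C4", "C"], ["C5", "C"],
            ["H2", "H"], ["H4", "H"], ["H5", "H"]],
  "params": [
    {"id": "O1C2", "kind": "bond", "atoms": ["O1", "C2"],
     "values": {"SE": 1.35097, "revDSD": 1.3548, "PW6B95": 1.3487},
     "sigma": {"SE": 0.00030}},
    {"id": "C2N3", "kind": "bond", "atoms": ["C2", "N3"],
     "values": {"SE": 1.28819, "revDSD": 1.2926, "PW6B95": 1.2897},
     "sigma": {"SE": 0.00027}},
    {"id": "C4N3", "kind": "bond", "atoms": ["N3", "C4"],
     "values": {"SE": 1.39268, "revDSD": 1.3945, "PW6B95": 1.3848},
     "sigma": {"SE": 0.00030}},
    {"id": "C4C5", "kind": "bond", "atoms": ["C4", "C5"],
     "values": {"SE": 1.34934, "revDSD": 1.3531, "PW6B95": 1.3528},
     "sigma": {"SE": 0.00020}},
    {"id": "C2H2", "kind": "bond", "atoms": ["C2", "H2"],
     "values": {"SE": 1.07481, "revDSD": 1.0774, "PW6B95": 1.0800},
     "sigma": {"SE": 0.00026}},
    {"id": "C4H4", "kind": "bond", "atoms": ["C4", "H4"],
     "values": {"SE": 1.07433, "revDSD": 1.0767, "PW6B95": 1.0804},
     "sigma": {"SE": 0.00026}, "predicate": true},
    {"id": "C5H5", "kind": "bond", "atoms": ["C5", "H5"],
     "values": {"SE": 1.07300, "revDSD": 1.0752, "PW6B95": 1.0785},
     "sigma": {"SE": 0.00058}, "predicate": true},
    {"id": "NCO", "kind": "angle", "atoms": ["N3", "C2", "O1"],
     "values": {"SE": 115.076, "revDSD": 114.93, "PW6B95": 114.65},
     "sigma": {"SE": 0.019}},
    {"id": "CNC", "kind": "angle", "atoms": ["C2", "N3", "C4"],
     "values": {"SE": 103.884, "revDSD": 103.94, "PW6B95": 104.13},
     "sigma": {"SE": 0.017}},
    {"id": "CCN", "kind": "angle", "atoms": ["C5", "C4", "N3"],
     "values": {"SE": 109.003, "revDSD": 109.04, "PW6B95": 109.06},
     "sigma": {"SE": 0.020}},
    {"id": "HCO", "kind": "angle", "atoms": ["H2", "C2", "O1"],
     "values": {"SE": 116.832, "revDSD": 116.74, "PW6B95": 116.88},
     "sigma": {"SE": 0.020}},
    {"id": "HCN", "kind": "angle", "atoms": ["H4", "C4", "N3"],
     "values": {"SE": 121.867, "revDSD": 121.93, "PW6B95": 122.06},
     "sigma": {"SE": 0.061}, "predicate": true},
    {"id": "HCC", "kind": "angle", "atoms": ["H5", "C5", "C4"],
     "values": {"SE": 135.145, "revDSD": 135.16, "PW6B95": 135.21},
     "sigma": {"SE": 0.061}, "predicate": true},
    {"id": "C4N3C2O1", "kind": "torsion", "atoms": ["C4", "N3", "C2", "O1"],
     "values": {"all": 0.0}, "completed": true},
    {"id": "C5C4N3C2", "kind": "torsion", "atoms": ["C5", "C4", "N3", "C2"],
     "values": {"all": 0.0}, "completed": true},
    {"id": "H2C2O1N3", "kind": "torsion", "atoms": ["H2", "C2", "O1", "N3"],
     "values": {"all": 180.0}, "completed": true, "improper": true},
    {"id": "H4C4N3C2", "kind": "torsion", "atoms": ["H4", "C4", "N3", "C2"],
     "values": {"all": 180.0}, "completed": true},
    {"id": "H5C5C4N3", "kind": "torsion", "atoms": ["H5", "C5", "C4", "N3"],
     "values": {"all": 180.0}, "completed": true}
  ],
  "placements": [
    {"atom": "O1"},
    {"atom": "C2", "dist": "O1C2"},
    {"atom": "N3", "dist": "C2N3", "ang": "NCO"},
    {"atom": "C4", "dist": "C4N3", "ang": "CNC", "tors": "C4N3C2O1"},
    {"atom": "C5", "dist": "C4C5", "ang": "CCN", "tors": "C5C4N3C2"},
    {"atom": "H2", "dist": "C2H2", "ang": "HCO", "tors": "H2C2O1N3"},
    {"atom": "H4", "dist": "C4H4", "ang": "HCN", "tors": "H4C4N3C2"},
    {"atom": "H5", "dist": "C5H5", "ang": "HCC", "tors": "H5C5C4N3"}
  ],
  "planar": true
}
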