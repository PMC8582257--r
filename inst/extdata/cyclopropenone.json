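{
  "id": "cyclopropenone",
  "name": "cyclopropenone",
  "description": "C2v planar three-membered ring ketone; the published table lists symmetry-unique values, duplicated here over the two equivalent CH carbons.",
  "levels": ["SE", "revDSD", "PW6B95"],
  "atoms": [["C1", "C"], ["O4", "O"], ["C2", "C"], ["C3", "C"], ["H5", "H"], ["H6", "H"]],
  "params": [
    {"id": "CO", "kind": "bond", "atoms": ["C1", "O4"],
     "values": {"SE": 1.20043, "revDSD": 1.2044, "PW6B95": 1.2024},
     "sigma": {"SE": 0.00013}},
    {"id": "C1C2", "kind": "bond", "atoms": ["C1", "C2"],
     "values": {"SE": 1.42887, "revDSD": 1.4350, "PW6B95": 1.4298},
     "sigma": {"SE": 0.00042},
     "label_misprint": "published label reads C2-C3; the value is chemically consistent with the two equivalent C1-C2/C1-C3 single bonds (the C2=C3 distance is implied by the CCO angle)"},
    {"id": "C1C3", "kind": "bond", "atoms": ["C1", "C3"],
     "values": {"SE": 1.42887, "revDSD": 1.4350, "PW6B95": 1.4298},
     "sigma": {"SE": 0.00042}, "symmetry_duplicate": "C1C2"},
    {"id": "C2H5", "kind": "bond", "atoms": ["C2", "H5"],
     "values": {"SE": 1.078173, "revDSD": 1.0814, "PW6B95": 1.0862},
     "sigma": {"SE": 0.000054}},
    {"id": "C3H6", "kind": "bond", "atoms": ["C3", "H6"],
     "values": {"SE": 1.078173, "revDSD": 1.0814, "PW6B95": 1.0862},
     "sigma": {"SE": 0.000054}, "symmetry_duplicate": "C2H5"},
    {"id": "CCO", "kind": "angle", "atoms": ["O4", "C1", "C2"],
     "values": {"SE": 151.9272, "revDSD": 151.93, "PW6B95": 151.91},
     "sigma": {"SE": 0.0023}},
    {"id": "CCO2", "kind": "angle", "atoms": ["O4", "C1", "C3"],
     "values": {"SE": 151.9272, "revDSD": 151.93, "PW6B95": 151.91},
     "sigma": {"SE": 0.0023}, "symmetry_duplicate": "CCO"},
    {"id": "CCH", "kind": "angle", "atoms": ["C1", "C2", "H5"],
     "values": {"SE": 153.7200, "revDSD": 153.78, "PW6B95": 153.86},
     "sigma": {"SE": 0.0064},
     "note": "interpreted as the H-C-C(carbonyl) angle; the published label does not state the attachment"},
    {"id": "CCH2", "kind": "angle", "atoms": ["C1", "C3", "H6"],
     "values": {"SE": 153.7200, "revDSD": 153.78, "PW6B95": 153.86},
     "sigma": {"SE": 0.0064}, "symmetry_duplicate": "CCH"},
    {"id": "C3C1O4C2", "kind": "torsion", "atoms": ["C3", "C1", "O4", "C2"],
     "values": {"all": 180.0}, "completed": true},
    {"id": "H5C2C1C3", "kind": "torsion", "atoms": ["H5", "C2", "C1", "C3"],
     "values": {"all": 180.0}, "completed": true},
    {"id": "H6C3C1C2", "kind": "torsion", "atoms": ["H6", "C3", "C1", "C2"],
     "values": {"all": 180.0}, "completed": true}
  ],
  "placements": [
    {"atom": "C1"},
    {"atom": "O4", "dist": "CO"},
    {"atom": "C2", "dist": "C1C2", "ang": "CCO"},
    {"atom": "C3", "dist": "C1C3", "ang": "CCO2", "tors": "C3C1O4C2"},
    {"atom": "H5", "dist": "C2H5", "ang": "CCH", "tors": "H5C2C1C3"},
    {"atom": "H6", "dist": "C3H6", "ang": "CCH2", "tors": "H6C3C1C2"}
  ],
  "planar": true
}
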