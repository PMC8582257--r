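{
  "id": "BH2OH",
  "name": "borinic acid",
  "description": "Planar molecule; semi-experimental fit used predicate observations for the O-H and B-H distances and the BOH angle.",
  "levels": ["SE", "revDSD", "PW6B95"],
  "atoms": [["B1", "B"], ["H2", "H"], ["H3", "H"], ["O4", "O"], ["H5", "H"]],
  "params": [
    {"id": "BH1", "kind": "bond", "atoms": ["B1", "H2"],
     "values": {"SE": 1.1957, "revDSD": 1.1982, "PW6B95": 1.2044},
     "sigma": {"SE": 0.0016}, "predicate": true},
    {"id": "BH2", "kind": "bond", "atoms": ["B1", "H3"],
     "values": {"SE": 1.1899, "revDSD": 1.1926, "PW6B95": 1.1997},
     "sigma": {"SE": 0.0016}, "predicate": true},
    {"id": "BO", "kind": "bond", "atoms": ["B1", "O4"],
     "values": {"SE": 1.34979, "revDSD": 1.3569, "PW6B95": 1.3524},
     "sigma": {"SE": 0.00013}},
    {"id": "OH", "kind": "bond", "atoms": ["O4", "H5"],
     "values": {"SE": 0.9558, "revDSD": 0.9614, "PW6B95": 0.9600},
     "sigma": {"SE": 0.0017}, "predicate": true},
    {"id": "HBH", "kind": "angle", "atoms": ["H2", "B1", "H3"],
     "values": {"SE": 122.84, "revDSD": 122.77, "PW6B95": 123.02},
     "sigma": {"SE": 0.15}},
    {"id": "HBO", "kind": "angle", "atoms": ["H2", "B1", "O4"],
     "values": {"SE": 119.80, "revDSD": 120.49, "PW6B95": 120.35},
     "sigma": {"SE": 0.23},
     "note": "assigned to the H2 (longer B-H) hydrogen; the published table does not label which"},
    {"id": "HOB", "kind": "angle", "atoms": ["B1", "O4", "H5"],
     "values": {"SE": 112.90, "revDSD": 112.94, "PW6B95": 113.18},
     "sigma": {"SE": 0.19}, "predicate": true},
    {"id": "OBHH", "kind": "torsion", "atoms": ["O4", "B1", "H2", "H3"],
     "values": {"all": 180.0}, "completed": true},
    {"id": "HOBH", "kind": "torsion", "atoms": ["H5", "O4", "B1", "H2"],
     "values": {"all": 180.0}, "completed": true,
     "note": "planar conformation choice: hydroxyl hydrogen anti to H2"}
  ],
  "placements": [
    {"atom": "B1"},
    {"atom": "H2", "dist": "BH1"},
    {"atom": "H3", "dist": "BH2", "ang": "HBH"},
    {"atom": "O4", "dist": "BO", "ang": "HBO", "tors": "OBHH"},
    {"atom": "H5", "dist": "OH", "ang": "HOB", "tors": "HOBH"}
  ],
  "planar": true
}
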