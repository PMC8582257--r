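{
  "id": "formaldoxime",
  "name": "formaldoxime",
  "description": "Planar H2C=N-OH; semi-experimental fit used only B and C constants with predicate observations for the O-H, NOH and C-H2 parameters.",
  "levels": ["SE", "revDSD", "PW6B95"],
  "atoms": [["C1", "C"], ["N2", "N"], ["O3", "O"], ["H1", "H"], ["H2", "H"], ["H3", "H"]],
  "params": [
    {"id": "CN", "kind": "bond", "atoms": ["C1", "N2"],
     "values": {"SE": 1.27112, "revDSD": 1.2728, "PW6B95": 1.2679},
     "sigma": {"SE": 0.00042}},
    {"id": "NO", "kind": "bond", "atoms": ["N2", "O3"],
     "values": {"SE": 1.39899, "revDSD": 1.4005, "PW6B95": 1.3867},
     "sigma": {"SE": 0.00035}},
    {"id": "CH1", "kind": "bond", "atoms": ["C1", "H1"],
     "values": {"SE": 1.08425, "revDSD": 1.0873, "PW6B95": 1.0918},
     "sigma": {"SE": 0.00047}},
    {"id": "CH2", "kind": "bond", "atoms": ["C1", "H2"],
     "values": {"SE": 1.07952, "revDSD": 1.0814, "PW6B95": 1.0858},
     "sigma": {"SE": 0.00064}, "predicate": true},
    {"id": "OH3", "kind": "bond", "atoms": ["O3", "H3"],
     "values": {"SE": 0.9627, "revDSD": 0.9627, "PW6B95": 0.9607},
     "sigma": {"SE": 0.0012}, "predicate": true},
    {"id": "CNO", "kind": "angle", "atoms": ["C1", "N2", "O3"],
     "values": {"SE": 110.548, "revDSD": 110.87, "PW6B95": 111.31},
     "sigma": {"SE": 0.015}},
    {"id": "H1CN", "kind": "angle", "atoms": ["H1", "C1", "N2"],
     "values": {"SE": 122.238, "revDSD": 122.47, "PW6B95": 122.54},
     "sigma": {"SE": 0.043}},
    {"id": "H2CN", "kind": "angle", "atoms": ["H2", "C1", "N2"],
     "values": {"SE": 116.223, "revDSD": 116.33, "PW6B95": 116.52},
     "sigma": {"SE": 0.077}},
    {"id": "H3ON", "kind": "angle", "atoms": ["N2", "O3", "H3"],
     "values": {"SE": 102.65, "revDSD": 102.61, "PW6B95": 103.41},
     "sigma": {"SE": 0.11}, "predicate": true},
    {"id": "ONCH1", "kind": "torsion", "atoms": ["H1", "C1", "N2", "O3"],
     "values": {"all": 180.0}, "completed": true,
     "note": "H1 assigned anti to the oxime oxygen; the published table does not state the assignment"},
    {"id": "ONCH2", "kind": "torsion", "atoms": ["H2", "C1", "N2", "O3"],
     "values": {"all": 0.0}, "completed": true},
    {"id": "H3ONC", "kind": "torsion", "atoms": ["H3", "O3", "N2", "C1"],
     "values": {"all": 180.0}, "completed": true,
     "note": "anti (trans) hydroxyl conformation"}
  ],
  "placements": [
    {"atom": "C1"},
    {"atom": "N2", "dist": "CN"},
    {"atom": "O3", "dist": "NO", "ang": "CNO"},
    {"atom": "H1", "dist": "CH1", "ang": "H1CN", "tors": "ONCH1"},
    {"atom": "H2", "dist": "CH2", "ang": "H2CN", "tors": "ONCH2"},
    {"atom": "H3", "dist": "OH3", "ang": "H3ON", "tors": "H3ONC"}
  ],
  "planar": true
}
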