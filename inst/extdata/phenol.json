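{
  "id": "phenol",
  "name": "phenol",
  "description": "Planar aromatic ring with hydroxyl group; the semi-experimental fit was staged, with several ring and CCH angles introduced as predicate observations (flagged 'fixed').",
  "levels": ["SE", "revDSD", "PW6B95"],
  "atoms": [["C1", "C"], ["C2", "C"], ["C3", "C"], ["C4", "C"], ["C5", "C"],
            ["C6", "C"], ["O1", "O"], ["H7", "H"], ["H2", "H"], ["H3", "H"],
            ["H4", "H"], ["H5", "H"], ["H6", "H"]],
  "params": [
    {"id": "C1C2", "kind": "bond", "atoms": ["C1", "C2"],
     "values": {"SE": 1.39197, "revDSD": 1.3941, "PW6B95": 1.3927},
     "sigma": {"SE": 0.00064}},
    {"id": "C2C3", "kind": "bond", "atoms": ["C2", "C3"],
     "values": {"SE": 1.39010, "revDSD": 1.3937, "PW6B95": 1.3910},
     "sigma": {"SE": 0.00043}},
    {"id": "C3C4", "kind": "bond", "atoms": ["C3", "C4"],
     "values": {"SE": 1.39018, "revDSD": 1.3921, "PW6B95": 1.3902},
     "sigma": {"SE": 0.00043}},
    {"id": "C4C5", "kind": "bond", "atoms": ["C4", "C5"],
     "values": {"SE": 1.39170, "revDSD": 1.3951, "PW6B95": 1.3929},
     "sigma": {"SE": 0.00043}},
    {"id": "C5C6", "kind": "bond", "atoms": ["C5", "C6"],
     "values": {"SE": 1.38882, "revDSD": 1.3943, "PW6B95": 1.3926},
     "sigma": {"SE": 0.00037}},
    {"id": "C1O1", "kind": "bond", "atoms": ["C1", "O1"],
     "values": {"SE": 1.36386, "revDSD": 1.3681, "PW6B95": 1.3632},
     "sigma": {"SE": 0.00028}},
    {"id": "O1H7", "kind": "bond", "atoms": ["O1", "H7"],
     "values": {"SE": 0.95939, "revDSD": 0.9624, "PW6B95": 0.9600},
     "sigma": {"SE": 0.00050}},
    {"id": "C2H2", "kind": "bond", "atoms": ["C2", "H2"],
     "values": {"SE": 1.08363, "revDSD": 1.0856, "PW6B95": 1.0888},
     "sigma": {"SE": 0.00033}},
    {"id": "C3H3", "kind": "bond", "atoms": ["C3", "H3"],
     "values": {"SE": 1.08090, "revDSD": 1.0836, "PW6B95": 1.0870},
     "sigma": {"SE": 0.00022}},
    {"id": "C4H4", "kind": "bond", "atoms": ["C4", "H4"],
     "values": {"SE": 1.07960, "revDSD": 1.0826, "PW6B95": 1.0859},
     "sigma": {"SE": 0.00016}},
    {"id": "C5H5", "kind": "bond", "atoms": ["C5", "H5"],
     "values": {"SE": 1.08133, "revDSD": 1.0836, "PW6B95": 1.0870},
     "sigma": {"SE": 0.00023}},
    {"id": "C6H6", "kind": "bond", "atoms": ["C6", "H6"],
     "values": {"SE": 1.07972, "revDSD": 1.0828, "PW6B95": 1.0859},
     "sigma": {"SE": 0.00030}},
    {"id": "C1C2C3", "kind": "angle", "atoms": ["C1", "C2", "C3"],
     "values": {"SE": 119.68, "revDSD": 119.68, "PW6B95": 119.65},
     "fixed": ["SE"], "predicate": true},
    {"id": "C2C3C4", "kind": "angle", "atoms": ["C2", "C3", "C4"],
     "values": {"SE": 120.50, "revDSD": 120.50, "PW6B95": 120.56},
     "fixed": ["SE"], "predicate": true},
    {"id": "C3C4C5", "kind": "angle", "atoms": ["C3", "C4", "C5"],
     "values": {"SE": 119.30, "revDSD": 119.30, "PW6B95": 119.22},
     "fixed": ["SE"], "predicate": true},
    {"id": "C4C5C6", "kind": "angle", "atoms": ["C4", "C5", "C6"],
     "values": {"SE": 120.79, "revDSD": 120.74, "PW6B95": 120.83},
     "fixed": ["SE"], "predicate": true},
    {"id": "C2C1O1", "kind": "angle", "atoms": ["C2", "C1", "O1"],
     "values": {"SE": 122.42, "revDSD": 122.45, "PW6B95": 122.44},
     "fixed": ["SE"], "predicate": true},
    {"id": "C1O1H7", "kind": "angle", "atoms": ["C1", "O1", "H7"],
     "values": {"SE": 108.907, "revDSD": 108.94, "PW6B95": 109.43},
     "sigma": {"SE": 0.019}},
    {"id": "C3C2H2", "kind": "angle", "atoms": ["C3", "C2", "H2"],
     "values": {"SE": 120.507, "revDSD": 120.31, "PW6B95": 120.38},
     "sigma": {"SE": 0.041}},
    {"id": "C4C3H3", "kind": "angle", "atoms": ["C4", "C3", "H3"],
     "values": {"SE": 120.164, "revDSD": 120.17, "PW6B95": 120.14},
     "sigma": {"SE": 0.024}},
    {"id": "C5C4H4", "kind": "angle", "atoms": ["C5", "C4", "H4"],
     "values": {"SE": 120.37, "revDSD": 120.37, "PW6B95": 120.43},
     "fixed": ["SE"], "predicate": true},
    {"id": "C6C5H5", "kind": "angle", "atoms": ["C6", "C5", "H5"],
     "values": {"SE": 119.286, "revDSD": 119.28, "PW6B95": 119.24},
     "sigma": {"SE": 0.025}},
    {"id": "C1C6H6", "kind": "angle", "atoms": ["C1", "C6", "H6"],
     "values": {"SE": 119.05, "revDSD": 119.04, "PW6B95": 119.24},
     "fixed": ["SE"], "predicate": true},
    {"id": "C4C3C2C1", "kind": "torsion", "atoms": ["C4", "C3", "C2", "C1"],
     "values": {"all": 0.0}, "completed": true},
    {"id": "C5C4C3C2", "kind": "torsion", "atoms": ["C5", "C4", "C3", "C2"],
     "values": {"all": 0.0}, "completed": true},
    {"id": "C6C5C4C3", "kind": "torsion", "atoms": ["C6", "C5", "C4", "C3"],
     "values": {"all": 0.0}, "completed": true},
    {"id": "O1C1C2C3", "kind": "torsion", "atoms": ["O1", "C1", "C2", "C3"],
     "values": {"all": 180.0}, "completed": true},
    {"id": "H7O1C1C2", "kind": "torsion", "atoms": ["H7", "O1", "C1", "C2"],
     "values": {"all": 0.0}, "completed": true,
     "note": "in-plane hydroxyl oriented toward C2; the published table does not state the orientation relative to the asymmetric CCH angles"},
    {"id": "H2C2C3C4", "kind": "torsion", "atoms": ["H2", "C2", "C3", "C4"],
     "values": {"all": 180.0}, "completed": true},
    {"id": "H3C3C4C5", "kind": "torsion", "atoms": ["H3", "C3", "C4", "C5"],
     "values": {"all": 180.0}, "completed": true},
    {"id": "H4C4C5C6", "kind": "torsion", "atoms": ["H4", "C4", "C5", "C6"],
     "values": {"all": 180.0}, "completed": true},
    {"id": "H5C5C6C1", "kind": "torsion", "atoms": ["H5", "C5", "C6", "C1"],
     "values": {"all": 180.0}, "completed": true},
    {"id": "H6C6C1C2", "kind": "torsion", "atoms": ["H6", "C6", "C1", "C2"],
     "values": {"all": 180.0}, "completed": true}
  ],
  "placements": [
    {"atom": "C1"},
    {"atom": "C2", "dist": "C1C2"},
    {"atom": "C3", "dist": "C2C3", "ang": "C1C2C3"},
    {"atom": "C4", "dist": "C3C4", "ang": "C2C3C4", "tors": "C4C3C2C1"},
    {"atom": "C5", "dist": "C4C5", "ang": "C3C4C5", "tors": "C5C4C3C2"},
    {"atom": "C6", "dist": "C5C6", "ang": "C4C5C6", "tors": "C6C5C4C3"},
    {"atom": "O1", "dist": "C1O1", "ang": "C2C1O1", "tors": "O1C1C2C3"},
    {"atom": "H7", "dist": "O1H7", "ang": "C1O1H7", "tors": "H7O1C1C2"},
    {"atom": "H2", "dist": "C2H2", "ang": "C3C2H2", "tors": "H2C2C3C4"},
    {"atom": "H3", "dist": "C3H3", "ang": "C4C3H3", "tors": "H3C3C4C5"},
    {"atom": "H4", "dist": "C4H4", "ang": "C5C4H4", "tors": "H4C4C5C6"},
    {"atom": "H5", "dist": "C5H5", "ang": "C6C5H5", "tors": "H5C5C6C1"},
    {"atom": "H6", "dist": "C6H6", "ang": "C1C6H6", "tors": "H6C6C1C2"}
  ],
  "planar": true
}
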