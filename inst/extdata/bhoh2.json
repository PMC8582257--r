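{
  "id": "BH(OH)2",
  "name": "boronic acid",
  "description": "Planar molecule with two inequivalent hydroxyl groups.",
  "levels": ["SE", "revDSD", "PW6B95"],
  "atoms": [["B2", "B"], ["H1", "H"], ["O3", "O"], ["O4", "O"], ["H5", "H"], ["H6", "H"]],
  "params": [
    {"id": "B2H1", "kind": "bond", "atoms": ["B2", "H1"],
     "values": {"SE": 1.189723, "revDSD": 1.1936, "PW6B95": 1.1986},
     "sigma": {"SE": 0.000080}},
    {"id": "BO3", "kind": "bond", "atoms": ["B2", "O3"],
     "values": {"SE": 1.35353, "revDSD": 1.3608, "PW6B95": 1.3574},
     "sigma": {"SE": 0.00019}},
    {"id": "BO4", "kind": "bond", "atoms": ["B2", "O4"],
     "values": {"SE": 1.36364, "revDSD": 1.3709, "PW6B95": 1.3674},
     "sigma": {"SE": 0.00017}},
    {"id": "O3H5", "kind": "bond", "atoms": ["O3", "H5"],
     "values": {"SE": 0.96034, "revDSD": 0.9634, "PW6B95": 0.9621},
     "sigma": {"SE": 0.00015}},
    {"id": "O4H6", "kind": "bond", "atoms": ["O4", "H6"],
     "values": {"SE": 0.95625, "revDSD": 0.9596, "PW6B95": 0.9580},
     "sigma": {"SE": 0.00024}},
    {"id": "H1B2O3", "kind": "angle", "atoms": ["H1", "B2", "O3"],
     "values": {"SE": 118.527, "revDSD": 118.534, "PW6B95": 118.658},
     "sigma": {"SE": 0.094}},
    {"id": "O3B2O4", "kind": "angle", "atoms": ["O3", "B2", "O4"],
     "values": {"SE": 119.1251, "revDSD": 119.171, "PW6B95": 118.877},
     "sigma": {"SE": 0.0041}},
    {"id": "B2O3H5", "kind": "angle", "atoms": ["B2", "O3", "H5"],
     "values": {"SE": 111.9132, "revDSD": 111.956, "PW6B95": 111.932},
     "sigma": {"SE": 0.0059}},
    {"id": "B2O4H6", "kind": "angle", "atoms": ["B2", "O4", "H6"],
     "values": {"SE": 116.223, "revDSD": 116.33, "PW6B95": 116.52},
     "sigma": {"SE": 0.077}},
    {"id": "O4B2O3H1", "kind": "torsion", "atoms": ["O4", "B2", "O3", "H1"],
     "values": {"all": 180.0}, "completed": true, "improper": true},
    {"id": "H5O3B2O4", "kind": "torsion", "atoms": ["H5", "O3", "B2", "O4"],
     "values": {"all": 180.0}, "completed": true,
     "note": "anti hydroxyl; planar syn/anti conformer choice"},
    {"id": "H6O4B2O3", "kind": "torsion", "atoms": ["H6", "O4", "B2", "O3"],
     "values": {"all": 0.0}, "completed": true,
     "note": "syn hydroxyl; planar syn/anti conformer choice"}
  ],
  "placements": [
    {"atom": "B2"},
    {"atom": "H1", "dist": "B2H1"},
    {"atom": "O3", "dist": "BO3", "ang": "H1B2O3"},
    {"atom": "O4", "dist": "BO4", "ang": "O3B2O4", "tors": "O4B2O3H1"},
    {"atom": "H5", "dist": "O3H5", "ang": "B2O3H5", "tors": "H5O3B2O4"},
    {"atom": "H6", "dist": "O4H6", "ang": "B2O4H6", "tors": "H6O4B2O3"}
  ],
  "planar": true
}
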