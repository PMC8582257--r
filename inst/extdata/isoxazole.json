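{
  "id": "isoxazole",
  "name": "isoxazole",
  "description": "Planar five-membered aromatic ring (1,2-oxazole); semi-experimental fit over A and B constants of all isotopologues.",
  "levels": ["SE", "revDSD", "PW6B95"],
  "atoms": [["O1", "O"], ["N2", "N"], ["C3", "C"], ["C4", "C"], ["C5", "C"],
            ["H6", "H"], ["H7", "H"], ["H8", "H"]],
  "params": [
    {"id": "O1N2", "kind": "bond", "atoms": ["O1", "N2"],
     "values": {"SE": 1.39274, "revDSD": 1.3930, "PW6B95": 1.3802},
     "sigma": {"SE": 0.00057}},
    {"id": "N2C3", "kind": "bond", "atoms": ["N2", "C3"],
     "values": {"SE": 1.30706, "revDSD": 1.3121, "PW6B95": 1.3064},
     "sigma": {"SE": 0.00085}},
    {"id": "C3C4", "kind": "bond", "atoms": ["C3", "C4"],
     "values": {"SE": 1.42101, "revDSD": 1.4213, "PW6B95": 1.4191},
     "sigma": {"SE": 0.00061}},
    {"id": "C4C5", "kind": "bond", "atoms": ["C4", "C5"],
     "values": {"SE": 1.3515, "revDSD": 1.3577, "PW6B95": 1.3564},
     "sigma": {"SE": 0.0010}},
    {"id": "C3H3", "kind": "bond", "atoms": ["C3", "H6"],
     "values": {"SE": 1.07590, "revDSD": 1.0793, "PW6B95": 1.0831},
     "sigma": {"SE": 0.00050}},
    {"id": "C4H4", "kind": "bond", "atoms": ["C4", "H7"],
     "values": {"SE": 1.07311, "revDSD": 1.0759, "PW6B95": 1.0795},
     "sigma": {"SE": 0.00054}},
    {"id": "C5H5", "kind": "bond", "atoms": ["C5", "H8"],
     "values": {"SE": 1.07556, "revDSD": 1.0777, "PW6B95": 1.0813},
     "sigma": {"SE": 0.00090}},
    {"id": "CNO", "kind": "angle", "atoms": ["C3", "N2", "O1"],
     "values": {"SE": 105.518, "revDSD": 105.41, "PW6B95": 105.48},
     "sigma": {"SE": 0.042}},
    {"id": "CCN", "kind": "angle", "atoms": ["C4", "C3", "N2"],
     "values": {"SE": 112.159, "revDSD": 112.20, "PW6B95": 112.16},
     "sigma": {"SE": 0.057}},
    {"id": "CCC", "kind": "angle", "atoms": ["C5", "C4", "C3"],
     "values": {"SE": 102.986, "revDSD": 103.003, "PW6B95": 102.79},
     "sigma": {"SE": 0.054}},
    {"id": "HCN", "kind": "angle", "atoms": ["H6", "C3", "N2"],
     "values": {"SE": 118.50, "revDSD": 118.71, "PW6B95": 118.78},
     "sigma": {"SE": 0.13}},
    {"id": "H7C4C3", "kind": "angle", "atoms": ["H7", "C4", "C3"],
     "values": {"SE": 128.44, "revDSD": 128.77, "PW6B95": 128.87},
     "sigma": {"SE": 0.13}},
    {"id": "H8C5C4", "kind": "angle", "atoms": ["H8", "C5", "C4"],
     "values": {"SE": 133.52, "revDSD": 133.64, "PW6B95": 133.62},
     "sigma": {"SE": 0.24}},
    {"id": "C4C3N2O1", "kind": "torsion", "atoms": ["C4", "C3", "N2", "O1"],
     "values": {"all": 0.0}, "completed": true},
    {"id": "C5C4C3N2", "kind": "torsion", "atoms": ["C5", "C4", "C3", "N2"],
     "values": {"all": 0.0}, "completed": true},
    {"id": "H6C3N2O1", "kind": "torsion", "atoms": ["H6", "C3", "N2", "O1"],
     "values": {"all": 180.0}, "completed": true},
    {"id": "H7C4C3N2", "kind": "torsion", "atoms": ["H7", "C4", "C3", "N2"],
     "values": {"all": 180.0}, "completed": true},
    {"id": "H8C5C4C3", "kind": "torsion", "atoms": ["H8", "C5", "C4", "C3"],
     "values": {"all": 180.0}, "completed": true}
  ],
  "placements": [
    {"atom": "O1"},
    {"atom": "N2", "dist": "O1N2"},
    {"atom": "C3", "dist": "N2C3", "ang": "CNO"},
    {"atom": "C4", "dist": "C3C4", "ang": "CCN", "tors": "C4C3N2O1"},
    {"atom": "C5", "dist": "C4C5", "ang": "CCC", "tors": "C5C4C3N2"},
    {"atom": "H6", "dist": "C3H3", "ang": "HCN", "tors": "H6C3N2O1"},
    {"atom": "H7", "dist": "C4H4", "ang": "H7C4C3", "tors": "H7C4C3N2"},
    {"atom": "H8", "dist": "C5H5", "ang": "H8C5C4", "tors": "H8C5C4C3"}
  ],
  "planar": true,
  "notes": [
    "Published hydrogen labels mix two conventions (C3-H3 bond vs H7C4C3 angle); atoms are labeled H6/H7/H8 here with the published parameter ids retained."
  ]
}
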