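{
  "id": "BHFOH",
  "name": "fluorohydroxyborane",
  "description": "Planar molecule; semi-experimental refit used predicate values for the B-F distance and HBF angle.",
  "levels": ["SE", "revDSD", "PW6B95"],
  "atoms": [["B1", "B"], ["H2", "H"], ["F3", "F"], ["O4", "O"], ["H5", "H"]],
  "params": [
    {"id": "BH", "kind": "bond", "atoms": ["B1", "H2"],
     "values": {"SE": 1.189385, "revDSD": 1.1932, "PW6B95": 1.1973},
     "sigma": {"SE": 0.000049}},
    {"id": "BF", "kind": "bond", "atoms": ["B1", "F3"],
     "values": {"SE": 1.31961, "revDSD": 1.3265, "PW6B95": 1.3390},
     "sigma": {"SE": 0.00015}, "predicate": true},
    {"id": "BO", "kind": "bond", "atoms": ["B1", "O4"],
     "values": {"SE": 1.34626, "revDSD": 1.3537, "PW6B95": 1.3478},
     "sigma": {"SE": 0.00015}},
    {"id": "OH", "kind": "bond", "atoms": ["O4", "H5"],
     "values": {"SE": 0.95735, "revDSD": 0.9603, "PW6B95": 0.9590},
     "sigma": {"SE": 0.00016}},
    {"id": "HBF", "kind": "angle", "atoms": ["H2", "B1", "F3"],
     "values": {"SE": 119.381, "revDSD": 119.37, "PW6B95": 119.14},
     "sigma": {"SE": 0.044}, "predicate": true},
    {"id": "HBO", "kind": "angle", "atoms": ["H2", "B1", "O4"],
     "values": {"SE": 123.459, "revDSD": 123.48, "PW6B95": 124.38},
     "sigma": {"SE": 0.044}},
    {"id": "HOB", "kind": "angle", "atoms": ["B1", "O4", "H5"],
     "values": {"SE": 112.714, "revDSD": 112.76, "PW6B95": 113.07},
     "sigma": {"SE": 0.018}},
    {"id": "OBHF", "kind": "torsion", "atoms": ["O4", "B1", "H2", "F3"],
     "values": {"all": 180.0}, "completed": true},
    {"id": "HOBF", "kind": "torsion", "atoms": ["H5", "O4", "B1", "F3"],
     "values": {"all": 180.0}, "completed": true,
     "note": "hydroxyl hydrogen anti to fluorine; planar conformation choice"}
  ],
  "placements": [
    {"atom": "B1"},
    {"atom": "H2", "dist": "BH"},
    {"atom": "F3", "dist": "BF", "ang": "HBF"},
    {"atom": "O4", "dist": "BO", "ang": "HBO", "tors": "OBHF"},
    {"atom": "H5", "dist": "OH", "ang": "HOB", "tors": "HOBF"}
  ],
  "planar": true
}
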