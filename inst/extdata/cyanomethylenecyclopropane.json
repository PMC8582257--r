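{
  "id": "cyanomethylenecyclopropane",
  "name": "(cyanomethylene)cyclopropane",
  "description": "Published equilibrium internal coordinates of the Cs-symmetric prebiotic molecule at two DFT levels and after LRA/TMA correction; only symmetry-unique parameters are published, the mirror-related ring carbon and hydrogens are generated by reflection through the heavy-atom plane.",
  "levels": ["revDSD", "PW6B95", "revDSD-LRA", "PW6B95-LRA", "revDSD-TMA", "PW6B95-TMA"],
  "atoms": [
    ["C3", "C"], ["C4", "C"], ["C1", "C"], ["N2", "N"], ["H7", "H"],
    ["C5", "C"], ["C6", "C"], ["H8", "H"], ["H10", "H"], ["H9", "H"],
    ["H11", "H"]
  ],
  "params": [
    {"id": "C1N2", "kind": "bond", "atoms": ["C1", "N2"],
     "values": {"revDSD": 1.1633, "PW6B95": 1.1592, "revDSD-LRA": 1.1605, "PW6B95-LRA": 1.1582, "revDSD-TMA": 1.1591, "PW6B95-TMA": 1.1598}},
    {"id": "C1C3", "kind": "bond", "atoms": ["C1", "C3"],
     "values": {"revDSD": 1.4324, "PW6B95": 1.4265, "revDSD-LRA": 1.4296, "PW6B95-LRA": 1.7272, "revDSD-TMA": 1.4297, "PW6B95-TMA": 1.4300},
     "misprint": {"level": "PW6B95-LRA", "printed": 1.7272, "plausible": 1.4272}},
    {"id": "C3C4", "kind": "bond", "atoms": ["C3", "C4"],
     "values": {"revDSD": 1.3273, "PW6B95": 1.3276, "revDSD-LRA": 1.3252, "PW6B95-LRA": 1.3267, "revDSD-TMA": 1.3255, "PW6B95-TMA": 1.3278}},
    {"id": "C4C5", "kind": "bond", "atoms": ["C4", "C5"],
     "values": {"revDSD": 1.4626, "PW6B95": 1.4580, "revDSD-LRA": 1.4596, "PW6B95-LRA": 1.4591, "revDSD-TMA": 1.4589, "PW6B95-TMA": 1.4589}},
    {"id": "C5C6", "kind": "bond", "atoms": ["C5", "C6"],
     "values": {"revDSD": 1.5388, "PW6B95": 1.5320, "revDSD-LRA": 1.5354, "PW6B95-LRA": 1.5343, "revDSD-TMA": 1.5351, "PW6B95-TMA": 1.5329},
     "closure": true},
    {"id": "C3H7", "kind": "bond", "atoms": ["C3", "H7"],
     "values": {"revDSD": 1.0833, "PW6B95": 1.0872, "revDSD-LRA": 1.0809, "PW6B95-LRA": 1.0809, "revDSD-TMA": 1.0806, "PW6B95-TMA": 1.0801}},
    {"id": "C5H8", "kind": "bond", "atoms": ["C5", "H8"],
     "values": {"revDSD": 1.0837, "PW6B95": 1.0875, "revDSD-LRA": 1.0811, "PW6B95-LRA": 1.0811, "revDSD-TMA": 1.0810, "PW6B95-TMA": 1.0807}},
    {"id": "C5H9", "kind": "bond", "atoms": ["C6", "H10"],
     "values": {"revDSD": 1.0836, "PW6B95": 1.0874, "revDSD-LRA": 1.0811, "PW6B95-LRA": 1.0811, "revDSD-TMA": 1.0809, "PW6B95-TMA": 1.0806},
     "label_misprint": "published label reads C5H9; under the molecular-plane mirror symmetry the second C5 hydrogen equals H8 exactly, so this value is assigned to the inequivalent C6 methylene (H10/H11)"},
    {"id": "C1C3C4", "kind": "angle", "atoms": ["C1", "C3", "C4"],
     "values": {"revDSD": 121.41, "PW6B95": 121.81, "revDSD-LRA": 121.38, "PW6B95-LRA": 121.69, "revDSD-TMA": 121.14, "PW6B95-TMA": 121.12}},
    {"id": "C3C4C5", "kind": "angle", "atoms": ["C3", "C4", "C5"],
     "values": {"revDSD": 148.31, "PW6B95": 148.16, "revDSD-LRA": 148.28, "PW6B95-LRA": 148.01, "revDSD-TMA": 148.24, "PW6B95-TMA": 148.01}},
    {"id": "C4C5C6", "kind": "angle", "atoms": ["C4", "C5", "C6"],
     "values": {"revDSD": 58.19, "PW6B95": 58.23, "revDSD-LRA": 58.18, "PW6B95-LRA": 58.17, "revDSD-TMA": 58.18, "PW6B95-TMA": 58.17},
     "closure": true},
    {"id": "C3C4H7", "kind": "angle", "atoms": ["C4", "C3", "H7"],
     "values": {"revDSD": 121.49, "PW6B95": 121.32, "revDSD-LRA": 121.49, "PW6B95-LRA": 121.29, "revDSD-TMA": 121.77, "PW6B95-TMA": 121.75},
     "label_misprint": "published label reads C3C4H7, but H7 is bonded to C3; interpreted as the C4-C3-H7 angle"},
    {"id": "C4C5H8", "kind": "angle", "atoms": ["C4", "C5", "H8"],
     "values": {"revDSD": 118.22, "PW6B95": 118.38, "revDSD-LRA": 118.22, "PW6B95-LRA": 118.35, "revDSD-TMA": 118.17, "PW6B95-TMA": 118.15}},
    {"id": "C5C6H10", "kind": "angle", "atoms": ["C5", "C6", "H10"],
     "values": {"revDSD": 117.76, "PW6B95": 118.10, "revDSD-LRA": 117.76, "PW6B95-LRA": 118.07, "revDSD-TMA": 117.71, "PW6B95-TMA": 117.87}},
    {"id": "C3C4C5H8", "kind": "torsion", "atoms": ["C3", "C4", "C5", "H8"],
     "values": {"revDSD": 73.31, "PW6B95": 71.97}},
    {"id": "C4C5C6H10", "kind": "torsion", "atoms": ["C4", "C5", "C6", "H10"],
     "values": {"revDSD": 107.48, "PW6B95": 107.52}},
    {"id": "N2C1C3", "kind": "angle", "atoms": ["N2", "C1", "C3"],
     "values": {"all": 180.0}, "completed": true,
     "note": "unpublished nitrile angle, completed as exactly linear; the dependent torsion is degenerate"},
    {"id": "H7C3C4C1", "kind": "torsion", "atoms": ["H7", "C3", "C4", "C1"],
     "values": {"all": 180.0}, "completed": true, "improper": true}
  ],
  "placements": [
    {"atom": "C3"},
    {"atom": "C4", "dist": "C3C4"},
    {"atom": "C1", "dist": "C1C3", "ang": "C1C3C4"},
    {"atom": "N2", "dist": "C1N2", "ang": "N2C1C3"},
    {"atom": "H7", "dist": "C3H7", "ang": "C3C4H7", "tors": "H7C3C4C1"},
    {"atom": "C5", "derive": "ring_closure", "dist": "C4C5", "closure": "C5C6",
     "ang_atoms": ["C3", "C4", "C5"],
     "tors_tuple": ["C5", "C4", "C3", "C1"], "tors_value": 0.0},
    {"atom": "C6", "derive": "ring_closure", "dist_from": "C4C5",
     "dist_ref": "C4", "closure": "C5C6", "ang_atoms": ["C3", "C4", "C6"],
     "tors_tuple": ["C6", "C4", "C3", "C1"], "tors_value": 180.0},
    {"atom": "H8", "dist": "C5H8", "ang": "C4C5H8", "tors": "C3C4C5H8"},
    {"atom": "H10", "dist": "C5H9", "ang": "C5C6H10", "tors": "C4C5C6H10"},
    {"reflect": {"plane": ["C3", "C4", "C1"], "map": {"H8": "H9", "H10": "H11"}}}
  ],
  "dvib": {"A": -80.314, "B": -3.747, "C": -5.216},
  "experimental": {"A": 12644.003, "B": 2038.862, "C": 1797.043},
  "constants_printed": {
    "revDSD": [12657.507, 2024.628, 1786.367],
    "PW6B95": [12778.564, 2024.199, 1788.412],
    "revDSD-LRA": [12647.603, 2038.517, 1796.792],
    "PW6B95-LRA": [12699.661, 2033.747, 1793.615],
    "revDSD-TMA": [12620.703, 2043.863, 1800.438],
    "PW6B95-TMA": [12628.917, 2039.953, 1797.156]
  },
  "mad_printed": {"revDSD": 0.47, "PW6B95": 0.75, "revDSD-LRA": 0.02, "PW6B95-LRA": 0.29, "revDSD-TMA": 0.21, "PW6B95-TMA": 0.06},
  "planar": false,
  "notes": [
    "All heavy atoms are coplanar (sp2 apex carbon): the Cs mirror is the molecular plane, generating the out-of-plane methylene hydrogens H9 (from H8, on C5) and H11 (from H10, on C6).",
    "The ring carbons C5/C6 are placed in-plane symmetrically about the C3=C4 axis from the published C4C5 and C5C6 distances; the implied C3C4C5 angle (e.g. 148.26 at the double-hybrid level) agrees with the published 148.31 within its printed rounding, and the measured C4C5C6 angle reproduces the published value to ~0.07 deg. C5 is taken cis to the nitrile.",
    "Torsion columns of the corrected levels are published as not available; corrected structures inherit torsions from the parent level.",
    "The hybrid-functional (PW6B95) constants row is not reproducible from the printed PW6B95 internal coordinates (up to 0.9% on A under every label reading tried), unlike the double-hybrid column and every other bundled molecule; the same table carries two flagged misprints. Constants checks for this molecule should use the double-hybrid column."
  ]
}
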