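{
  "8-hydroxyquinoline": {
    "file": "hydroxyquinoline8.json",
    "source": "semi-experimental refit and literature mass-dependent structure; template-corrected theory",
    "md5": "a42aa7b32299856bbcae0d36f63f3447"
  },
  "benzofuran": {
    "file": "benzofuran.json",
    "source": "semi-experimental structure from a template-guided refinement with fixed CH parameters",
    "md5": "3f91305517f291e93b981c102b76b40f"
  },
  "BH(OH)2": {
    "file": "bhoh2.json",
    "source": "new semi-experimental reference structure",
    "md5": "a4daf2b39ff2b6183d78bcc75a0a9a40"
  },
  "BH2OH": {
    "file": "bh2oh.json",
    "source": "new semi-experimental reference structure",
    "md5": "785184128ffa41cf7cfa100e7282929a"
  },
  "BHFOH": {
    "file": "bhfoh.json",
    "source": "new semi-experimental reference structure",
    "md5": "b82e11a50f5458b1a7ad900c70930442"
  },
  "cyanomethylenecyclopropane": {
    "file": "cyanomethylenecyclopropane.json",
    "source": "DFT equilibrium geometries with LRA/TMA corrections and experimental constants",
    "md5": "b14726ff6a7d32e623d4102821a3bb8f"
  },
  "cyclopropenone": {
    "file": "cyclopropenone.json",
    "source": "redetermined semi-experimental reference structure",
    "md5": "f9c3268ffe25598fe8f84099513a7c28"
  },
  "cysteine": {
    "file": "cysteine.json",
    "source": "DFT equilibrium geometries with LRA corrections and experimental constants (conformer IIb)",
    "md5": "131944e672304305e654c7b10597599d"
  },
  "formaldoxime": {
    "file": "formaldoxime.json",
    "source": "new semi-experimental reference structure (predicate-stabilized fit)",
    "md5": "2689656877df424f8371b6701c8334da"
  },
  "guanine": {
    "file": "guanine.json",
    "source": "DFT equilibrium geometries with LRA/TMA corrections and experimental constants (keto N7H)",
    "md5": "f13517f6a3142e38c4559d0611ef4750"
  },
  "isoxazole": {
    "file": "isoxazole.json",
    "source": "new semi-experimental reference structure",
    "md5": "0410021df2fc9e10dee6e425995777af"
  },
  "oxazole": {
    "file": "oxazole.json",
    "source": "new semi-experimental reference structure (predicate-stabilized fit)",
    "md5": "466879382ee0aa21a68307e4f98a27d5"
  },
  "phenol": {
    "file": "phenol.json",
    "source": "new semi-experimental reference structure (staged predicate fit)",
    "md5": "51a93a023842eeb2e42ef6b0574f7063"
  }
}
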