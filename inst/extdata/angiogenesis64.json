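{
  "model": "angiogenesis64",
  "description": "64-node synchronous Boolean model of endothelial cell behavior during sprouting angiogenesis; 16 micro-environment inputs held constant through identity self-loops.",
  "inputs": ["VEGFC_Dp", "VEGFAxxxP", "ANG1", "Oxygen", "ShearStress", "JAGp",
             "DLL4p", "WNT5a", "WNT7a", "FGF", "IGF", "BMP9", "BMP10",
             "TGFB1", "VEGFC_D", "AMPATP"],
  "environment_bit_order": "first listed input is the most significant bit of the environment code",
  "signatures": {
    "Tip": {"NRP1": 1, "DLL4a": 1, "AKT": 0},
    "Stalk": {"JAGa": 1, "NRP1": 0},
    "Phalanx": {"AKT": 1, "JAGa": 0, "NRP1": 0}
  },
  "proliferation_markers": ["betacatenin", "LEF1"],
  "display_names": {"betacatenin": "βcatenin"}
}
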