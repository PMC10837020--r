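{
  "species": "Triticum aestivum",
  "gm_ref": 5.5,
  "Ea_gm": 47.65,
  "Kair_ref": 772,
  "Ea_Kair": 93.72,
  "gammastar_ref": 37.74,
  "Ea_gammastar": 24.42,
  "pressure": 96,
  "T_ref": 298.15,
  "Ed_default": 200,
  "units": {
    "gm_ref": "umol m-2 s-1 Pa-1",
    "Kair_ref": "umol mol-1",
    "gammastar_ref": "umol mol-1",
    "Ea_*": "kJ mol-1",
    "pressure": "kPa",
    "T_ref": "K"
  }
}
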