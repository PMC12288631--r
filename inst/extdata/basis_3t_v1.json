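{
  "version": "1.0",
  "description": "Parametric 1H metabolite basis for 3 T: simplified multiplet models (chemical shifts in ppm, proton-weighted relative intensities, per-line Lorentz FWHM in Hz). Chemical shifts from standard literature compilations. T1/T2 are literature-style defaults in ms, configurable, not measured values.",
  "field_mhz": 123.25,
  "water_ppm": 4.68,
  "water_protons": 2,
  "metabolites": {
    "asp":    {"name": "aspartate",               "protons": 3, "t1_ms": 1220, "t2_ms": 180, "lines": [[2.652, 1], [2.801, 1], [3.891, 1]]},
    "cr":     {"name": "creatine",                "protons": 5, "t1_ms": 1240, "t2_ms": 162, "lines": [[3.027, 3], [3.913, 2]]},
    "gaba":   {"name": "GABA",                    "protons": 6, "t1_ms": 1310, "t2_ms": 180, "lines": [[1.889, 2], [2.284, 2], [3.011, 2]]},
    "glc":    {"name": "glucose",                 "protons": 4, "t1_ms": 1200, "t2_ms": 180, "lines": [[3.430, 2], [3.800, 2]]},
    "glu":    {"name": "glutamate",               "protons": 5, "t1_ms": 1270, "t2_ms": 180, "lines": [[2.120, 2], [2.340, 2], [3.746, 1]]},
    "gln":    {"name": "glutamine",               "protons": 5, "t1_ms": 1270, "t2_ms": 180, "lines": [[2.135, 2], [2.440, 2], [3.765, 1]]},
    "gsh":    {"name": "glutathione",             "protons": 6, "t1_ms": 1200, "t2_ms": 180, "lines": [[2.550, 2], [2.950, 2], [3.770, 2]]},
    "gly":    {"name": "glycine",                 "protons": 2, "t1_ms": 1200, "t2_ms": 180, "lines": [[3.548, 2]]},
    "gpc":    {"name": "glycerophosphorylcholine","protons": 11, "t1_ms": 1100, "t2_ms": 207, "lines": [[3.212, 9], [3.610, 2]]},
    "lac":    {"name": "lactate",                 "protons": 4, "t1_ms": 1550, "t2_ms": 240, "lines": [[1.313, 3], [4.097, 1]]},
    "mi":     {"name": "myo-inositol",            "protons": 7, "t1_ms": 1010, "t2_ms": 200, "lines": [[3.522, 2], [3.548, 2], [3.614, 2], [4.054, 1]]},
    "naa":    {"name": "NAA",                     "protons": 5, "t1_ms": 1470, "t2_ms": 247, "lines": [[2.008, 3], [2.486, 1], [2.673, 1]]},
    "naag":   {"name": "NAAG",                    "protons": 3, "t1_ms": 1470, "t2_ms": 247, "lines": [[2.042, 3]]},
    "pcr":    {"name": "phosphocreatine",         "protons": 5, "t1_ms": 1240, "t2_ms": 162, "lines": [[3.029, 3], [3.930, 2]]},
    "pcho":   {"name": "phosphorylcholine",       "protons": 11, "t1_ms": 1100, "t2_ms": 207, "lines": [[3.208, 9], [3.643, 2]]},
    "pe":     {"name": "phosphorylethanolamine",  "protons": 4, "t1_ms": 1200, "t2_ms": 180, "lines": [[3.216, 2], [3.977, 2]]},
    "scyllo": {"name": "scyllo-inositol",         "protons": 6, "t1_ms": 1200, "t2_ms": 240, "lines": [[3.340, 6]]},
    "tau":    {"name": "taurine",                 "protons": 4, "t1_ms": 1420, "t2_ms": 220, "lines": [[3.246, 2], [3.420, 2]]}
  },
  "default_line_lorentz_fwhm_hz": 2.0,
  "mmbg_hump_ppm":   [0.91, 1.21, 1.43, 1.72, 2.05, 2.29, 3.00, 3.21],
  "mmbg_hump_amp":   [1.00, 0.60, 0.45, 0.35, 0.45, 0.40, 0.35, 0.25],
  "mmbg_hump_fwhm_hz": [22, 25, 25, 28, 30, 30, 32, 32]
}
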