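{
  "version": "1.0",
  "description": "Population prior for flunixin IV disposition in horses: bootstrap typical values, full log-scale between-subject covariance matrix and combined residual-error magnitudes from a four-country meta-analysis (65 horses), three-compartment model with proportional urine channel.",
  "theta": {
    "V1": 121.0, "V2": 8.9, "V3": 31.68,
    "Cl": 47.36, "Cl2": 0.22, "Cl3": 7.54,
    "Rss": 35.93
  },
  "omega_order": ["V1", "Cl", "Cl2", "Cl3", "V2", "V3", "Rss"],
  "omega": [
    [ 0.032, 0.030, -0.016, -0.027, 0.047, 0.011,  0.083],
    [ 0.030, 0.085,  0.050,  0.030, 0.051, 0.032,  0.151],
    [-0.016, 0.050,  0.303,  0.237, 0.181, 0.117,  0.030],
    [-0.027, 0.030,  0.237,  0.352, 0.049, 0.190, -0.035],
    [ 0.047, 0.051,  0.181,  0.049, 0.335, 0.070,  0.098],
    [ 0.011, 0.032,  0.117,  0.190, 0.070, 0.140,  0.000],
    [ 0.083, 0.151,  0.030, -0.035, 0.098, 0.000,  0.683]
  ],
  "sigma": {
    "plasma_prop": 0.15, "plasma_add": 0.12,
    "urine_prop": 0.42, "urine_add": 0.11
  }
}
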