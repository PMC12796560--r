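{
  "version": "1.0",
  "description": "Screening-limit scenario set for flunixin: current IFHA international screening limits, candidate limits derived from the irrelevant plasma/urine concentrations, and the HISA and RMTC plasma limits paired with the IFHA urine limit.",
  "pairs": [
    {"label": "ifha-isl",      "plasma_SL": 1, "urine_SL": 100},
    {"label": "candidate-ipc", "plasma_SL": 2, "urine_SL": 70},
    {"label": "candidate-3",   "plasma_SL": 3, "urine_SL": 100},
    {"label": "hisa",          "plasma_SL": 4, "urine_SL": 100},
    {"label": "rmtc",          "plasma_SL": 5, "urine_SL": 100}
  ]
}
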