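{
  "components": [
    {"line": "HCT116", "fraction": 0.25},
    {"line": "MIA-PaCa-2", "fraction": 0.25},
    {"line": "H1975", "fraction": 0.25},
    {"line": "SK-MEL-28", "fraction": 0.25}
  ]
}
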