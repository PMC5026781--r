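{
  "family": "flanked",
  "params": {
    "gI": [0.02, 0.01],
    "gD": [0.03, 0.02, 0.01, 0.005, 0.002, 0.001]
  },
  "cutoffs": {
    "LI": 2,
    "LD": 6
  },
  "boundary": {
    "gIL": [0.02, 0.01],
    "gIR": [0.02, 0.01]
  },
  "time_profile": {
    "type": "constant"
  }
}
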