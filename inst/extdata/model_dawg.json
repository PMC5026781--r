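{
  "family": "dawg",
  "params": {
    "gI": [0.018, 0.0075, 0.0045],
    "gD": [0.02, 0.012, 0.008]
  },
  "cutoffs": {
    "LI": 3,
    "LD": 3
  },
  "boundary": {
    "gIL": [0.018, 0.0075, 0.0045],
    "gIR": [0.018, 0.0075, 0.0045]
  },
  "time_profile": {
    "type": "constant"
  }
}
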