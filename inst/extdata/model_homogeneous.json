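{
  "family": "homogeneous",
  "params": {
    "gI": [0.02, 0.01, 0.005],
    "gD": [0.03, 0.015, 0.007]
  },
  "cutoffs": {
    "LI": 3,
    "LD": 3
  },
  "boundary": {
    "gIL": [0.02, 0.01, 0.005],
    "gIR": [0.02, 0.01, 0.005]
  },
  "time_profile": {
    "type": "constant"
  }
}
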