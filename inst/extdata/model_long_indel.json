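{
  "family": "long_indel",
  "params": {
    "gI": [0.02, 0.00410381471114972, 0.00137322387191695, 0.000561376506114963],
    "gD": [0.03, 0.00923358310008687, 0.0046346305677197, 0.002841968562207],
    "whole": [0.0491592881014406, 0.0194395254009604, 0.00748793065244062, 0.00224550602445985]
  },
  "cutoffs": {
    "LI": 4,
    "LD": 4
  },
  "boundary": {
    "gIL": [0.0311401214866757, 0.00742674765778381, 0.00221528863108939, 0.000561376506114963],
    "gIR": [0.0311401214866757, 0.00742674765778381, 0.00221528863108939, 0.000561376506114963]
  },
  "time_profile": {
    "type": "constant"
  }
}
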