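A 1 2 - 4
B 1 2 3 4
C 1 2 3 4
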