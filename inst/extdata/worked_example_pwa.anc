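ancestor 1 2 3 4 5 6 - - - 7
descendant 1 - - - 5 6 8 9 10 7
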