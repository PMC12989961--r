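3.0,0.385
0.84,0.8087
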