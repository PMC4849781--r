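parameter	value
r1.k	0.02
r2.k	0.1
r3.k	0.1
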