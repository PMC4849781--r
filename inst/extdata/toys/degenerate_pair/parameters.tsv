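parameter	value
r1.k	0.2
r2.k	1
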