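parameter	value
r1.k	0.05
r1.kr	0.05
x1.k	0.04
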