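group	parameter	weight
k1	r1.k	0.02
k2	r2.k	0.1
k3	r3.k	0.05
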