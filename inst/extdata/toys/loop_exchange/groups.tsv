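group	parameter	weight
kx	x1.k	0.04
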