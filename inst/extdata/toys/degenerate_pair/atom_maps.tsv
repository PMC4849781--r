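reaction	substrate	product
r1	1.1	1.1
r1	1.2	1.2
r1	1.3	1.3
r2	1.1	1.1
r2	1.2	1.2
r2	1.3	1.3
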