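run	cell_line	meki	gf	replicate
A1	CL	0	0	1
A2	CL	0	0	2
A3	CL	0	0	3
B1	CL	1	0	1
B2	CL	1	0	2
B3	CL	1	0	3
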