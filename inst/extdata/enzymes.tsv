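name	recognition	top_cut	bottom_cut
EcoRI	GAATTC	1	5
MluCI	AATT	0	4
BbsI	GAAGAC	8	12
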