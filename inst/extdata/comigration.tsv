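scheme	species	band
BbsI-first	GGCGTGCTAT	10mer-T/C
BbsI-first	GGCGCGCTAT	10mer-T/C
BbsI-first	GGCGAGCTAT	10mer-A
BbsI-first	GGCGGGCTAT	10mer-G
BbsI-first	GGCGGCTAT	9mer
BbsI-first	GGCGCTAT	8mer
BbsI-first	GGCGATAAGCTAT	13mer
MluCI-first	AATTATAGCA	10mer-N.A
MluCI-first	AATTATAGCG	10mer-N.G
MluCI-first	AATTATAGCT	10mer-N.T
MluCI-first	AATTATAGCC	10mer-N.C
MluCI-first	AATTATAGC	9mer
MluCI-first	AATTATAG	8mer
MluCI-first	AATTATAGCTTAT	13mer
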