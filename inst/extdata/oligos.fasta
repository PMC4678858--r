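>lesion12mer
ATGGCGXGCTAT
>linker10mer
AGTGGAAGAC
>scaffold1
CTTCCACTCACTGAATCATGGTCATAGCTTTC
>scaffold2
AAAACGACGGCCAGTGAATTATAGC
>competitor25mer
GCAGGATGTCATGGCGATAAGCTAT
>fwdPrimer
CAGCTATGACCATGATTCAGTGAGTGGA
>revPrimer
TCGGTGCGGGCCTCTTCGCTATTAC
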