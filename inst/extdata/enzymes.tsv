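name	recognition	cut_offset_top	cut_offset_bottom
SbfI	CCTGCAGG	2	6
EcoRI	GAATTC	1	5
MluCI	AATT	0	4
MspI	CCGG	1	3
PstI	CTGCAG	5	1
AvaII	GGWCC	1	4
NlaIII	CATG	4	0
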