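gene	A549	PANC1
BAMBI	1	0
CBLC	0	0
EGFR	1	0
ERBB2	0	0
ITGB1	1	1
MAPK1	1	0
TLR2	1	1
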