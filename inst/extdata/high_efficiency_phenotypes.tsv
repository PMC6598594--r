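couple	phenotype	TGFB1	BAMBI	CBLC	EGFR	ERBB2	FOXO6	ITGB1	MAPK1	TLR2
1	7	1	0	0	0	0	0	0	0	0
1	248	1	0	0	0	0	1	0	0	0
2	13	1	0	1	0	0	0	0	0	0
2	291	1	0	1	0	0	1	0	0	0
3	24	1	0	0	0	1	0	0	0	0
3	348	1	0	0	0	1	1	0	0	0
4	77	1	0	1	0	1	0	0	0	0
4	343	1	0	1	0	1	1	0	0	0
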