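sex	line	group	n	mean	sd
F	CC	P1	8	1.86	0.35
F	RR	P2	8	0.00	0.00
F	CR	F1A	10	2.14	0.40
F	RC	F1B	15	1.65	0.70
M	CC	P1	10	1.90	0.37
M	RR	P2	9	0.00	0.00
M	CR	F1A	15	1.61	0.43
M	RC	F1B	10	2.42	0.45
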