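sample_id	group	gene	ct	replicate
P2_1	P2	GAPDH	19.9	1
P2_1	P2	GAPDH	20.0	2
P2_1	P2	GAPDH	20.1	3
P2_1	P2	HMGCL	24.9	1
P2_1	P2	HMGCL	25.0	2
P2_1	P2	HMGCL	25.1	3
P2_2	P2	GAPDH	20.0	1
P2_2	P2	GAPDH	20.0	2
P2_2	P2	GAPDH	20.0	3
P2_2	P2	HMGCL	25.0	1
P2_2	P2	HMGCL	25.0	2
P2_2	P2	HMGCL	25.0	3
P1_1	P1	GAPDH	20.0	1
P1_1	P1	GAPDH	20.0	2
P1_1	P1	GAPDH	20.0	3
P1_1	P1	HMGCL	24.0	1
P1_1	P1	HMGCL	24.0	2
P1_1	P1	HMGCL	24.0	3
F1A_1	F1A	GAPDH	20.1	1
F1A_1	F1A	GAPDH	20.0	2
F1A_1	F1A	GAPDH	19.9	3
F1A_1	F1A	HMGCL	23.1	1
F1A_1	F1A	HMGCL	23.0	2
F1A_1	F1A	HMGCL	22.9	3
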