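cross	line	type	count
F1A	CR	I	717
F1A	CR	II	355
F1A	CR	III	1
F1A	CR	IV	181
F1A	CR	V	0
F1A	CR	VI	0
F1A	CR	VII	11
F1A	CR	VIII	30
F1A	CR	IX	128
F1A	CR	X	0
F1A	CR	XI	305
F1A	CR	XII	587
F1B	RC	I	577
F1B	RC	II	402
F1B	RC	III	0
F1B	RC	IV	225
F1B	RC	V	3
F1B	RC	VI	1
F1B	RC	VII	28
F1B	RC	VIII	45
F1B	RC	IX	136
F1B	RC	X	3
F1B	RC	XI	435
F1B	RC	XII	608
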