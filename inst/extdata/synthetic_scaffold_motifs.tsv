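name	index	class	res1	res2
synthetic-scaffold	1	P	T	D
synthetic-scaffold	2	P	T	N
synthetic-scaffold	3	P	T	N
synthetic-scaffold	4	P	N	D
synthetic-scaffold	5	P	N	S
synthetic-scaffold	6	P	N	S
synthetic-scaffold	7	P	T	D
synthetic-scaffold	8	P	N	D
synthetic-scaffold	9	P	T	N
synthetic-scaffold	10	P	N	D
synthetic-scaffold	11	P	T	D
synthetic-scaffold	12	P	T	D
synthetic-scaffold	13	P	N	S
synthetic-scaffold	14	P	T	N
synthetic-scaffold	15	P	N	D
synthetic-scaffold	16	P	N	S
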