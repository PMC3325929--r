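motif	parent	1185	4769	8281-8289	14022	16126	16189	16217	16247	16261
B4a1a1c	B4a1a1	.	G	-	G	C	C	C	.	T
B4a1a1a	B4a1a1	.	G	-	G	.	C	C	G	T
B4a1a1a3	B4a1a1a	T	.	-	G	.	C	C	G	T
B4a1a1a5	B4a1a1a	.	G	-	G	C	C	C	G	T
Polynesian-motif	B4a1a1	-	-	d	-	-	C	C	G	T
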