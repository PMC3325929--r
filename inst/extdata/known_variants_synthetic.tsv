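position	alt	source
73	G	synthetic-catalog
146	C	synthetic-catalog
151	T	synthetic-catalog
263	G	synthetic-catalog
750	G	synthetic-catalog
1185	T	synthetic-catalog
1438	G	synthetic-catalog
1692	G	synthetic-catalog
2416	C	synthetic-catalog
2706	G	synthetic-catalog
4769	G	synthetic-catalog
5465	C	synthetic-catalog
6261	A	synthetic-catalog
6719	C	synthetic-catalog
6905	G	synthetic-catalog
7028	T	synthetic-catalog
8281	del	synthetic-catalog
8860	G	synthetic-catalog
8865	A	synthetic-catalog
9123	A	synthetic-catalog
9145	A	synthetic-catalog
14022	G	synthetic-catalog
16126	C	synthetic-catalog
16189	C	synthetic-catalog
16217	C	synthetic-catalog
16247	G	synthetic-catalog
16261	T	synthetic-catalog
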