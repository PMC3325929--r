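sample	73	146	151	263	750	1185	1438	1692	1806	2416	2706	3909	4769!	5465	6261	6719	6782	6905	7028	8860	8865	9123	9145
CRS	A	T	C	A	A	C	A	A	T	T	A	C	A	T	G	T	T	A	C	A	G	G	G
mt3	G	C	.	G	G	T	G	.	.	.	G	.	.	C	.	C	.	.	T	G	.	A	.
mt6	G	C	.	G	G	.	G	.	.	.	G	.	G	C	.	C	.	.	T	G	.	A	.
mt8	G	C	.	G	G	T	G	.	.	.	G	.	.	C	.	C	.	.	T	G	.	A	.
mt9	G	C	.	G	G	.	G	.	.	.	G	T	G	C	.	C	.	.	T	G	.	A	.
mt10	G	C	T	G	G	.	G	G	.	C	G	.	G	C	.	C	.	.	T	G	.	A	.
mt11	G	C	.	G	G	.	G	.	.	.	G	.	G	C	.	C	.	.	T	G	A	A	.
mt12	G	C	.	G	G	.	G	.	.	.	G	.	G	C	.	C	.	.	T	G	A	A	.
mt13	G	C	.	G	G	T	G	.	.	.	G	.	.	C	.	C	.	.	T	G	.	A	.
mt14	G	C	.	G	G	T	G	.	.	.	G	.	.	C	.	C	.	.	T	G	.	A	.
mt16	G	C	.	G	G	.	G	.	.	.	G	.	G	C	.	C	.	.	T	G	.	A	.
mt18	G	C	.	G	G	.	G	.	.	.	G	.	G	C	A	C	.	G	T	G	.	A	A
mt19	G	C	.	G	G	.	G	.	.	.	G	T	G	C	A	C	.	.	T	G	.	A	.
mt21	G	C	.	G	G	.	G	.	.	.	G	T	G	C	.	C	.	.	T	G	.	A	.
mt23	G	C	.	G	G	.	G	.	.	.	G	.	G	C	.	C	.	.	T	G	.	A	.
mt24	G	C	.	G	G	.	G	.	.	.	G	.	G	C	.	C	.	.	T	G	.	A	.
mt25	G	C	.	G	G	T	G	.	.	.	G	.	.	C	.	C	.	.	T	G	.	A	.
mt26	G	C	.	G	G	.	G	.	.	.	G	.	G	C	.	C	C	.	T	G	.	A	.
mt28	G	C	.	G	G	T	G	.	.	.	G	.	.	C	.	C	.	.	T	G	.	A	.
mt29	G	C	.	G	G	T	G	.	C	C	G	.	.	C	.	C	.	.	T	G	.	A	.
mt30	G	C	T	G	G	.	G	G	.	.	G	.	G	C	.	C	.	.	T	G	.	A	.
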