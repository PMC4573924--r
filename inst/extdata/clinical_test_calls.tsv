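sample_id	chrom	pos	ref	alt	gene	observed_pct	depth	quality	strand_bias	hgvs_c
DNA_01	chr7	55249071	C	T	EGFR	19.3	917	2111	0.56	c.2369C>T
DNA_02	chr7	55241708	G	C	EGFR	26.6	934	2222	0.57	c.2156G>C
DNA_05	chr7	55248999	A	AGCCAGCGTG	EGFR	33.9	951	2333	0.58	c.2307_2308ins9
DNA_08	chr7	55249071	C	T	EGFR	41.2	968	2444	0.59	c.2369C>T
DNA_09	chr7	55249071	C	T	EGFR	48.5	985	2555	0.6	c.2369C>T
DNA_10	chr7	55242465	GGAATTAAGAGAAGCA	G	EGFR	15.8	1002	2666	0.61	c.2236_2250del15
DNA_21	chr12	25398284	C	A	KRAS	23.1	1019	2777	0.62	c.35G>T
DNA_23	chr7	55259524	T	A	EGFR	30.4	1036	2888	0.63	c.2582T>A
DNA_24	chr7	55259524	T	A	EGFR	37.7	1053	2999	0.64	c.2582T>A
DNA_26	chr7	140453136	T	A	BRAF	45	1070	3110	0.65	c.1799T>A
DNA_27	chr12	25398285	C	T	KRAS	12.3	1087	3221	0.66	c.34G>A
DNA_29	chr7	55241707	G	A	EGFR	19.6	1104	3332	0.67	c.2155G>A
DNA_32	chr12	25398285	C	A	KRAS	26.9	1121	3443	0.68	c.34G>T
DNA_33	chr7	140453135	TG	AA	BRAF	34.2	1138	3554	0.69	c.1798_1799delGTinsAA
DNA_34	chr7	140453135	TG	AA	BRAF	41.5	1155	3665	0.7	c.1798_1799delGTinsAA
DNA_35	chr7	55242464	AGGAATTAAGAGA	A	EGFR	48.8	1172	3776	0.71	c.2235_2246del12
DNA_37	chr7	55259515	T	G	EGFR	16.1	1189	3887	0.72	c.2573T>G
DNA_38	chr7	55259515	T	G	EGFR	23.4	1206	3998	0.73	c.2573T>G
DNA_39	chr12	25398285	C	A	KRAS	30.7	1223	4109	0.74	c.34G>T
DNA_41	chr12	25398281	C	T	KRAS	38	1240	4220	0.55	c.38G>A
DNA_42	chr12	25398281	C	T	KRAS	45.3	1257	4331	0.56	c.38G>A
DNA_43	chr7	55259515	T	G	EGFR	3.5	1274	4442	0.57	c.2573T>G
DNA_44	chr7	55249004	A	AACC	EGFR	19.9	1291	4553	0.58	c.2312_2314dupACC
DNA_47	chr12	25398284	C	A	KRAS	27.2	1308	4664	0.59	c.35G>T
DNA_50	chr7	140453136	T	A	BRAF	34.5	1325	4775	0.6	c.1799T>A
DNA_51	chr12	25398284	C	T	KRAS	41.8	1342	4886	0.61	c.35G>A
DNA_52	chr7	140453136	T	A	BRAF	49.1	1359	4997	0.62	c.1799T>A
DNA_53	chr12	25398284	C	A	KRAS	16.4	1376	5108	0.63	c.35G>T
DNA_54	chr7	55259515	T	G	EGFR	23.7	1393	5219	0.64	c.2573T>G
DNA_55	chr7	140453136	T	A	BRAF	31	1410	5330	0.65	c.1799T>A
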