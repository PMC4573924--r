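sample_id	gene	status	hgvs_c
DNA_01	KRAS	negative	.
DNA_01	EGFR	positive	c.2369C>T
DNA_01	BRAF	negative	.
DNA_02	KRAS	negative	.
DNA_02	EGFR	positive	c.2156G>C
DNA_02	BRAF	negative	.
DNA_03	KRAS	negative	.
DNA_03	EGFR	negative	.
DNA_03	BRAF	negative	.
DNA_04	KRAS	negative	.
DNA_04	EGFR	negative	.
DNA_04	BRAF	negative	.
DNA_05	KRAS	negative	.
DNA_05	EGFR	positive	c.2307_2308ins9
DNA_05	BRAF	negative	.
DNA_06	KRAS	negative	.
DNA_06	EGFR	negative	.
DNA_06	BRAF	negative	.
DNA_07	KRAS	negative	.
DNA_07	EGFR	negative	.
DNA_07	BRAF	negative	.
DNA_08	KRAS	negative	.
DNA_08	EGFR	positive	c.2369C>T
DNA_08	BRAF	negative	.
DNA_09	KRAS	negative	.
DNA_09	EGFR	positive	c.2369C>T
DNA_09	BRAF	negative	.
DNA_10	KRAS	negative	.
DNA_10	EGFR	positive	c.2236_2250del15
DNA_10	BRAF	negative	.
DNA_11	KRAS	negative	.
DNA_11	EGFR	negative	.
DNA_11	BRAF	negative	.
DNA_12	KRAS	negative	.
DNA_12	EGFR	negative	.
DNA_12	BRAF	negative	.
DNA_13	KRAS	negative	.
DNA_13	EGFR	negative	.
DNA_13	BRAF	negative	.
DNA_14	KRAS	negative	.
DNA_14	EGFR	negative	.
DNA_14	BRAF	negative	.
DNA_15	KRAS	negative	.
DNA_15	EGFR	negative	.
DNA_15	BRAF	negative	.
DNA_16	KRAS	negative	.
DNA_16	EGFR	negative	.
DNA_16	BRAF	negative	.
DNA_17	KRAS	negative	.
DNA_17	EGFR	negative	.
DNA_17	BRAF	negative	.
DNA_18	KRAS	negative	.
DNA_18	EGFR	negative	.
DNA_18	BRAF	negative	.
DNA_19	KRAS	negative	.
DNA_19	EGFR	negative	.
DNA_19	BRAF	negative	.
DNA_20	KRAS	negative	.
DNA_20	EGFR	negative	.
DNA_20	BRAF	negative	.
DNA_21	KRAS	positive	c.35G>T
DNA_21	EGFR	negative	.
DNA_21	BRAF	negative	.
DNA_22	KRAS	negative	.
DNA_22	EGFR	negative	.
DNA_22	BRAF	negative	.
DNA_23	KRAS	negative	.
DNA_23	EGFR	positive	c.2582T>A
DNA_23	BRAF	negative	.
DNA_24	KRAS	negative	.
DNA_24	EGFR	positive	c.2582T>A
DNA_24	BRAF	negative	.
DNA_25	KRAS	negative	.
DNA_25	EGFR	negative	.
DNA_25	BRAF	negative	.
DNA_26	KRAS	negative	.
DNA_26	EGFR	negative	.
DNA_26	BRAF	positive	c.1799T>A
DNA_27	KRAS	positive	c.34G>A
DNA_27	EGFR	negative	.
DNA_27	BRAF	negative	.
DNA_28	KRAS	negative	.
DNA_28	EGFR	negative	.
DNA_28	BRAF	negative	.
DNA_29	KRAS	negative	.
DNA_29	EGFR	positive	c.2155G>A
DNA_29	BRAF	negative	.
DNA_30	KRAS	negative	.
DNA_30	EGFR	negative	.
DNA_30	BRAF	negative	.
DNA_31	KRAS	negative	.
DNA_31	EGFR	negative	.
DNA_31	BRAF	negative	.
DNA_32	KRAS	positive	c.34G>T
DNA_32	EGFR	negative	.
DNA_32	BRAF	negative	.
DNA_33	KRAS	negative	.
DNA_33	EGFR	negative	.
DNA_33	BRAF	positive	c.1798_1799delGTinsAA
DNA_34	KRAS	negative	.
DNA_34	EGFR	negative	.
DNA_34	BRAF	positive	c.1798_1799delGTinsAA
DNA_35	KRAS	negative	.
DNA_35	EGFR	positive	c.2235_2246del12
DNA_35	BRAF	negative	.
DNA_36	KRAS	negative	.
DNA_36	EGFR	negative	.
DNA_36	BRAF	negative	.
DNA_37	KRAS	negative	.
DNA_37	EGFR	positive	c.2573T>G
DNA_37	BRAF	negative	.
DNA_38	KRAS	negative	.
DNA_38	EGFR	positive	c.2573T>G
DNA_38	BRAF	negative	.
DNA_39	KRAS	positive	c.34G>T
DNA_39	EGFR	negative	.
DNA_39	BRAF	negative	.
DNA_40	KRAS	negative	.
DNA_40	EGFR	negative	.
DNA_40	BRAF	negative	.
DNA_41	KRAS	positive	c.38G>A
DNA_41	EGFR	negative	.
DNA_41	BRAF	negative	.
DNA_42	KRAS	positive	c.38G>A
DNA_42	EGFR	negative	.
DNA_42	BRAF	negative	.
DNA_43	KRAS	negative	.
DNA_43	EGFR	positive	c.2573T>G
DNA_43	BRAF	negative	.
DNA_44	KRAS	negative	.
DNA_44	EGFR	positive	c.2312_2314dupACC
DNA_44	BRAF	negative	.
DNA_45	KRAS	negative	.
DNA_45	EGFR	negative	.
DNA_45	BRAF	negative	.
DNA_46	KRAS	negative	.
DNA_46	EGFR	negative	.
DNA_46	BRAF	negative	.
DNA_47	KRAS	positive	c.35G>T
DNA_47	EGFR	negative	.
DNA_47	BRAF	negative	.
DNA_48	KRAS	negative	.
DNA_48	EGFR	negative	.
DNA_48	BRAF	negative	.
DNA_49	KRAS	negative	.
DNA_49	EGFR	negative	.
DNA_49	BRAF	negative	.
DNA_50	KRAS	negative	.
DNA_50	EGFR	negative	.
DNA_50	BRAF	positive	c.1799T>A
DNA_51	KRAS	positive	c.35G>A
DNA_51	EGFR	negative	.
DNA_51	BRAF	negative	.
DNA_52	KRAS	negative	.
DNA_52	EGFR	negative	.
DNA_52	BRAF	positive	c.1799T>A
DNA_53	KRAS	positive	c.35G>T
DNA_53	EGFR	negative	.
DNA_53	BRAF	negative	.
DNA_54	KRAS	negative	.
DNA_54	EGFR	positive	c.2573T>G
DNA_54	BRAF	negative	.
DNA_55	KRAS	negative	.
DNA_55	EGFR	negative	.
DNA_55	BRAF	positive	c.1799T>A
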