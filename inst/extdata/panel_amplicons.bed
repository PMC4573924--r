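track name=panel_amplicons description="synthetic amplicon target regions"
chr5	149433400	149433600	CSF1R_AMPL1
chr7	140453050	140453250	BRAF_AMPL1
chr7	55242400	55242600	EGFR_AMPL1
chr7	55249000	55249200	EGFR_AMPL2
chr7	55259400	55259600	EGFR_AMPL3
chr12	25398200	25398400	KRAS_AMPL1
chr3	41266050	41266250	CTNNB1_AMPL1
chr3	178952000	178952200	PIK3CA_AMPL1
chr10	89711800	89711900	PTEN_AMPL1
chr19	1220250	1220450	STK11_AMPL1
chr13	48953750	48953950	RB1_AMPL1
chr4	1807800	1808000	FGFR3_AMPL1
chr13	28610100	28610300	FLT3_AMPL1
chr4	55141000	55141200	PDGFRA_AMPL1
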