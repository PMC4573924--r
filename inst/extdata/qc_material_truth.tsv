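gene	chrom	pos	ref	alt	mean_pct	sd_pct
BRAF	chr7	140453136	T	A	18.5	1.5
EGFR	chr7	55242487	C	T	17.1	1.4
EGFR	chr7	55249071	C	T	28.6	1.7
EGFR	chr7	55259515	T	G	23.4	1.5
KRAS	chr12	25398281	G	A	9.6	0.7
KRAS	chr12	25398285	C	T	37.9	1.1
PIK3CA	chr3	178952085	A	G	9.1	1.0
CTNNB1	chr3	41266134	ACTT	A	11.5	2.0
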