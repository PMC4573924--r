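line	chrom	pos	ref	alt	gene	freq_pct	copy_state
HCT116	chr9	133738370	A	G	ABL1	37.0	normal
HCT116	chr5	112175770	G	A	APC	98.0	normal
HCT116	chr5	149433596	A	C	CSF1R	100.0	normal
HCT116	chr5	149433597	C	T	CSF1R	95.7	normal
HCT116	chr3	41266134	ACTT	A	CTNNB1	44.9	normal
HCT116	chr7	55249063	G	A	EGFR	100.0	normal
HCT116	chr2	212812097	A	G	ERBB4	100.0	normal
HCT116	chr4	1807894	G	A	FGFR3	100.0	normal
HCT116	chr13	28602367	G	A	FLT3	49.5	normal
HCT116	chr13	28610183	T	C	FLT3	100.0	normal
HCT116	chr11	534242	T	C	HRAS	98.9	normal
HCT116	chr4	55946354	G	A	KDR	47.9	normal
HCT116	chr4	55972974	C	T	KDR	47.1	normal
HCT116	chr12	25398281	G	A	KRAS	47.7	normal
HCT116	chr4	55141055	A	G	PDGFRA	100.0	normal
HCT116	chr3	178952085	A	G	PIK3CA	47.7	normal
HCT116	chr10	43613843	C	T	RET	100.0	normal
HCT116	chr10	43615612	A	G	RET	49.1	normal
HCT116	chr18	48586344	C	T	SMAD4	50.6	normal
HCT116	chr22	24176287	G	A	SMARCB1	52.1	normal
HCT116	chr7	128846374	G	A	SMO	51.0	normal
HCT116	chr17	7579472	A	G	TP53	84.2	normal
MIA-PaCa-2	chr5	112175770	G	A	APC	72.7	normal
MIA-PaCa-2	chr9	21971153	C	T	CDKN2A	.	hom_deletion
MIA-PaCa-2	chr5	149433596	A	C	CSF1R	100.0	normal
MIA-PaCa-2	chr5	149433597	C	T	CSF1R	96.1	normal
MIA-PaCa-2	chr7	55249063	G	A	EGFR	35.6	normal
MIA-PaCa-2	chr4	1807894	G	A	FGFR3	100.0	normal
MIA-PaCa-2	chr13	28610183	T	C	FLT3	64.3	normal
MIA-PaCa-2	chr11	534242	T	C	HRAS	47.8	normal
MIA-PaCa-2	chr12	25398285	C	T	KRAS	100.0	normal
MIA-PaCa-2	chr7	116339672	C	T	MET	70.3	normal
MIA-PaCa-2	chr9	139390822	A	G	NOTCH1	100.0	normal
MIA-PaCa-2	chr4	55141055	A	G	PDGFRA	100.0	normal
MIA-PaCa-2	chr10	43613843	C	T	RET	67.5	normal
MIA-PaCa-2	chr10	43615633	A	G	RET	65.1	normal
MIA-PaCa-2	chr17	7577539	C	T	TP53	99.9	normal
H1975	chr5	112175770	G	A	APC	36.5	normal
H1975	chr9	21971153	C	T	CDKN2A	100.0	normal
H1975	chr5	149433596	A	C	CSF1R	100.0	normal
H1975	chr5	149433597	C	T	CSF1R	97.2	normal
H1975	chr7	55249063	G	A	EGFR	75.3	normal
H1975	chr7	55249071	C	T	EGFR	74.8	normal
H1975	chr7	55259515	T	G	EGFR	71.7	normal
H1975	chr2	212812097	A	G	ERBB4	72.3	normal
H1975	chr4	1807894	G	A	FGFR3	100.0	normal
H1975	chr13	28610183	T	C	FLT3	100.0	normal
H1975	chr11	534242	T	C	HRAS	38.9	normal
H1975	chr4	55141055	A	G	PDGFRA	100.0	normal
H1975	chr4	55152040	C	T	PDGFRA	51.3	normal
H1975	chr3	178917005	A	G	PIK3CA	100.0	normal
H1975	chr3	178927410	A	G	PIK3CA	47.1	normal
H1975	chr22	24176287	G	A	SMARCB1	46.3	normal
H1975	chr17	7577120	G	A	TP53	100.0	normal
H1975	chr17	7579472	A	G	TP53	90.8	normal
SK-MEL-28	chr5	112175770	G	A	APC	91.3	normal
SK-MEL-28	chr7	140453136	T	A	BRAF	100.0	normal
SK-MEL-28	chr7	55242487	C	T	EGFR	100.0	normal
SK-MEL-28	chr7	55249063	G	A	EGFR	100.0	normal
SK-MEL-28	chr4	1807894	G	A	FGFR3	100.0	normal
SK-MEL-28	chr13	28610183	T	C	FLT3	65.2	normal
SK-MEL-28	chr11	534242	T	C	HRAS	48.5	normal
SK-MEL-28	chr4	55141055	A	G	PDGFRA	100.0	normal
SK-MEL-28	chr10	89711881	A	G	PTEN	100.0	normal
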