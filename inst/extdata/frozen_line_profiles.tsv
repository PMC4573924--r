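line	chrom	pos	ref	alt	gene	freq_pct	copy_state
HCT116	chr9	133738370	A	G	ABL1	52.4	normal
HCT116	chr5	112175770	G	A	APC	98.1	normal
HCT116	chr5	149433596	A	C	CSF1R	99.6	normal
HCT116	chr5	149433597	C	T	CSF1R	99.6	normal
HCT116	chr3	41266134	ACTT	A	CTNNB1	50.2	normal
HCT116	chr7	55249063	G	A	EGFR	100.0	normal
HCT116	chr2	212812097	A	G	ERBB4	100.0	normal
HCT116	chr4	1807894	G	A	FGFR3	100.0	normal
HCT116	chr13	28602367	G	A	FLT3	46.9	normal
HCT116	chr13	28610183	T	C	FLT3	100.0	normal
HCT116	chr11	534242	T	C	HRAS	99.5	normal
HCT116	chr4	55946354	G	A	KDR	48.5	normal
HCT116	chr4	55972974	C	T	KDR	52.6	normal
HCT116	chr12	25398281	G	A	KRAS	46.4	normal
HCT116	chr4	55141055	A	G	PDGFRA	99.7	normal
HCT116	chr3	178952085	A	G	PIK3CA	47.7	normal
HCT116	chr10	43613843	C	T	RET	100.0	normal
HCT116	chr10	43615612	A	G	RET	45.2	normal
HCT116	chr18	48586344	C	T	SMAD4	47.6	normal
HCT116	chr22	24176287	G	A	SMARCB1	50.7	normal
HCT116	chr7	128846374	G	A	SMO	52.6	normal
HCT116	chr17	7579472	A	G	TP53	94.2	normal
MIA-PaCa-2	chr5	112175770	G	A	APC	74.4	normal
MIA-PaCa-2	chr5	149433596	A	C	CSF1R	99.3	normal
MIA-PaCa-2	chr5	149433597	C	T	CSF1R	99.1	normal
MIA-PaCa-2	chr7	55249063	G	A	EGFR	23.2	normal
MIA-PaCa-2	chr4	1807894	G	A	FGFR3	100.0	normal
MIA-PaCa-2	chr13	28610183	T	C	FLT3	66.5	normal
MIA-PaCa-2	chr11	534242	T	C	HRAS	61.9	normal
MIA-PaCa-2	chr12	25398285	C	T	KRAS	99.9	normal
MIA-PaCa-2	chr7	116339672	C	T	MET	72.9	normal
MIA-PaCa-2	chr9	139390822	A	G	NOTCH1	100.0	normal
MIA-PaCa-2	chr4	55141055	A	G	PDGFRA	100.0	normal
MIA-PaCa-2	chr10	43613843	C	T	RET	65.8	normal
MIA-PaCa-2	chr10	43615633	A	G	RET	64.5	normal
MIA-PaCa-2	chr17	7577539	C	T	TP53	99.5	normal
H1975	chr5	112175770	G	A	APC	51.7	normal
H1975	chr9	21971153	C	T	CDKN2A	96.4	normal
H1975	chr5	149433596	A	C	CSF1R	100.0	normal
H1975	chr5	149433597	C	T	CSF1R	100.0	normal
H1975	chr7	55249063	G	A	EGFR	70.6	normal
H1975	chr7	55249071	C	T	EGFR	70.7	normal
H1975	chr7	55259515	T	G	EGFR	56.7	normal
H1975	chr2	212812097	A	G	ERBB4	75.9	normal
H1975	chr4	1807894	G	A	FGFR3	99.6	normal
H1975	chr13	28610183	T	C	FLT3	99.6	normal
H1975	chr11	534242	T	C	HRAS	40.4	normal
H1975	chr4	55141055	A	G	PDGFRA	99.7	normal
H1975	chr4	55152040	C	T	PDGFRA	50.8	normal
H1975	chr3	178917005	A	G	PIK3CA	100.0	normal
H1975	chr3	178927410	A	G	PIK3CA	45.1	normal
H1975	chr22	24176287	G	A	SMARCB1	40.8	normal
H1975	chr17	7577120	G	A	TP53	99.9	normal
H1975	chr17	7579472	A	G	TP53	94.2	normal
SK-MEL-28	chr5	112175770	G	A	APC	88.5	normal
SK-MEL-28	chr7	140453136	T	A	BRAF	99.3	normal
SK-MEL-28	chr7	55242487	C	T	EGFR	99.3	normal
SK-MEL-28	chr7	55249063	G	A	EGFR	100.0	normal
SK-MEL-28	chr4	1807894	G	A	FGFR3	100.0	normal
SK-MEL-28	chr13	28610183	T	C	FLT3	69.2	normal
SK-MEL-28	chr11	534242	T	C	HRAS	46.9	normal
SK-MEL-28	chr4	55141055	A	G	PDGFRA	100.0	normal
SK-MEL-28	chr10	89711881	A	G	PTEN	99.3	normal
PLACENTA	chr5	112175770	G	A	APC	2.1	normal
PLACENTA	chr11	108138003	T	C	ATM	55.8	normal
PLACENTA	chr5	149433596	A	C	CSF1R	90.5	normal
PLACENTA	chr5	149433597	C	T	CSF1R	93.2	normal
PLACENTA	chr7	55249063	G	A	EGFR	97.6	normal
PLACENTA	chr2	212812097	A	G	ERBB4	62.9	normal
PLACENTA	chr4	1807894	G	A	FGFR3	100.0	normal
PLACENTA	chr13	28610183	T	C	FLT3	100.0	normal
PLACENTA	chr11	534242	T	C	HRAS	2.6	normal
PLACENTA	chr4	55946354	G	A	KDR	51.3	normal
PLACENTA	chr4	55141055	A	G	PDGFRA	99.9	normal
PLACENTA	chr4	55152040	C	T	PDGFRA	3.8	normal
PLACENTA	chr10	43613843	C	T	RET	100.0	normal
PLACENTA	chr17	7577025	C	T	TP53	79.0	normal
PLACENTA	chr17	7579472	A	G	TP53	20.4	normal
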