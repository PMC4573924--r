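gene	chrom	pos	ref	alt	rsid	maf
EGFR	chr7	55249063	G	A	rs1050171	0.4183
FGFR3	chr4	1807894	G	A	rs7688609	0.4600
FLT3	chr13	28610183	T	C	rs1933437	0.3400
PDGFRA	chr4	55141055	A	G	rs1873778	0.4500
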