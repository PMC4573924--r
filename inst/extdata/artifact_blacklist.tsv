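gene	chrom	pos	ref	alt	class
EGFR	chr7	55249063	G	A	HIGH_MAF_SNP
FGFR3	chr4	1807894	G	A	HIGH_MAF_SNP
FLT3	chr13	28610183	T	C	HIGH_MAF_SNP
PDGFRA	chr4	55141055	A	G	HIGH_MAF_SNP
CSF1R	chr5	149433596	A	C	END_OF_AMPLICON
CSF1R	chr5	149433597	C	T	END_OF_AMPLICON
STK11	chr19	1220321	T	C	HOMOPOLYMER
PTEN	chr10	89711834	A	AT	HOMOPOLYMER
RB1	chr13	48953805	CA	C	HOMOPOLYMER
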