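metric	mean	sd	confidence	z	side	transform	rounding	digits
coverage	1231	526	95	1.96	lower	identity	integer	.
q20_bases	2.5e7	2.4e6	95	1.96	lower	identity	signif	2
quality_log10	3.65	0.45	99	2.576	lower	log10	signif	1
strand_bias	0.7	0.04	99	2.326	upper	identity	decimals	2
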