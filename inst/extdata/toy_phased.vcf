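##fileformat=VCFv4.2
##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2
1	100	rs1	G	T	.	PASS	AA=G	GT	0|1	1|1
1	200	rs2	A	G	.	PASS	AA=G	GT	1|0	0|0
1	300	rs3	A	G	.	PASS	.	GT	0|0	1|0
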