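##fileformat=VCFv4.2
##source=coalabc
##contig=<ID=locus_000,length=1000>
##contig=<ID=locus_001,length=1000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	TIW_001	TIW_002	PNG_001
locus_000	1	.	A	T	.	PASS	.	GT	0|1	0|0	1|1
locus_000	500	.	A	T	.	PASS	.	GT	1|1	0|1	0|0
locus_000	1000	.	A	T	.	PASS	.	GT	0|0	.|.	0|1
locus_001	250	.	A	T	.	PASS	.	GT	0|1	1|0	0|0
locus_001	999	.	A	T	.	PASS	.	GT	1|0	0|0	1|1
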