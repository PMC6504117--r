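##fileformat=VCFv4.2
##source=antagwas
##contig=<ID=2L>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	line_001	line_002	line_003
2L	2294	.	T	C	.	PASS	.	GT:DP:GQ	0:30:99	0:30:99	1:30:99
2L	2922	.	G	T	.	PASS	.	GT:DP:GQ	0:30:99	1:30:99	0:30:99
2L	3043	.	A	G	.	PASS	.	GT:DP:GQ	0:30:99	1:30:99	0:30:99
2L	3298	.	C	T	.	PASS	.	GT:DP:GQ	0:30:99	1:30:99	0:30:99
2L	3884	.	T	G	.	PASS	.	GT:DP:GQ	0:30:99	0:30:99	1:30:99
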