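##fileformat=VCFv4.2
##contig=<ID=chrI,length=2000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	h1	h2	h3	h4	h5	h6	h7	h8
chrI	1005	.	A	T	.	PASS	.	GT	1	1	1	1	0	0	0	0
chrI	1050	.	C	G	.	PASS	.	GT	1	0	0	0	0	0	0	0
chrI	1250	.	G	A	.	PASS	.	GT	1	1	0	0	0	0	0	0
chrI	1260	.	T	C	.	PASS	.	GT	1	1	1	0	0	0	.	.
chrI	1270	.	A	G	.	PASS	.	GT	1	.	.	.	.	.	.	.
chrI	1550	.	C	T	.	PASS	.	GT	0	0	0	0	0	0	0	1
chrI	1700	.	G	C	.	PASS	.	GT	1	1	1	1	1	0	0	0
chrI	1800	.	A	AT	.	PASS	.	GT	0	0	0	0	0	0	0	1
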