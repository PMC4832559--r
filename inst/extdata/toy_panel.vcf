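##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	h01	h02	h03	h04	h05	h06	h07	h08	h09	h10	h11
chr1	1200	.	G	A	.	PASS	.	GT	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	1450	.	C	T	.	PASS	.	GT	0/0	0/0	0/1	0/1	0/0	0/0	./.	0/0	0/0	0/0	0/0
chr1	2100	.	T	C,G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0
chr2	510	.	A	G	.	PASS	.	GT	1/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
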