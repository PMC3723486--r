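##fileformat=VCFv4.2
##source=gxepower synthetic example (not real genotypes)
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4
16	53809247	rs1121980	C	T	.	PASS	.	GT	0/0	0/1	1/1	./.
16	28883241	rs7498665	G	A	.	PASS	.	GT	0/0	0/1	1/1	1/1
1	177913519	rs10913469	T	C	.	PASS	.	GT	0/1	0/0	1/1	0/1
11	47663049	rs10838738	A	G	.	PASS	.	GT	1/1	0/1	0/0	0/1
18	57851097	rs17782313	C	T	.	PASS	.	GT	0/0	1/1	0/1	0/0
1	72751185	rs3101336	T	C	.	PASS	.	GT	0/1	0/1	1/1	1/1
2	634905	rs6548238	C	T	.	PASS	.	GT	0/0	0/1	0/0	1/1
4	45182527	rs10938397	A	G	.	PASS	.	GT	0/1	1/1	0/1	0/0
11	27679916	rs925946	G	T	.	PASS	.	GT	0/1	0/0	0/1	1/1
19	34323231	rs368794	C	T	.	PASS	.	GT	1/1	0/1	0/0	0/1
3	185834290	rs7647305	T	C	.	PASS	.	GT	0/1	1/1	0/1	0/1
12	50247468	rs7132908	G	A	.	PASS	.	GT	0/0	0/1	1/1	0/1
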