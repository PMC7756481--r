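##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##contig=<ID=chr1>
##contig=<ID=chr3>
##contig=<ID=chr4>
##contig=<ID=chr5>
##contig=<ID=chr6>
##contig=<ID=chr7>
##contig=<ID=chr8>
##contig=<ID=chr9>
##contig=<ID=chr10>
##contig=<ID=chr11>
##contig=<ID=chr12>
##contig=<ID=chr13>
##contig=<ID=chr16>
##contig=<ID=chr17>
##contig=<ID=chr18>
##contig=<ID=chr19>
##contig=<ID=chr20>
##contig=<ID=chr21>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	SAMPLE1
chr1	1131672	.	G	C	96.2	PASS	.	GT	0/1
chr1	10557367	.	A	G	64.3	PASS	.	GT	0/1
chr1	12881710	.	G	A	95.2	PASS	.	GT	1/1
chr3	14633727	.	C	G	44.6	PASS	.	GT	0/1
chr3	34578051	.	C	T	66.5	PASS	.	GT	0/1
chr4	19082070	.	T	A	77.5	PASS	.	GT	0/1
chr4	21787606	.	C	G	67.7	PASS	.	GT	0/1
chr5	9261183	.	A	C	75.4	PASS	.	GT	0/1
chr5	13364237	.	T	A	78.6	PASS	.	GT	0/1
chr5	17870607	.	T	G	39	PASS	.	GT	1/1
chr5	36956684	.	A	G	59.8	PASS	.	GT	0/1
chr6	29323542	.	T	G	71.3	PASS	.	GT	0/1
chr6	30308288	.	A	T	52.3	PASS	.	GT	0/1
chr6	32810587	.	G	C	45.7	PASS	.	GT	0/1
chr7	27419541	.	G	T	44.5	PASS	.	GT	0/1
chr8	13210337	.	G	C	73.9	PASS	.	GT	0/1
chr8	29667101	.	T	G	31.6	PASS	.	GT	0/1
chr8	31863787	.	C	T	79.6	PASS	.	GT	0/1
chr9	3572055	.	T	C	73.7	PASS	.	GT	1/1
chr9	6193206	.	G	T	79.5	PASS	.	GT	0/1
chr9	18134983	.	C	G	39.9	PASS	.	GT	0/1
chr10	13926102	.	G	T	50.8	PASS	.	GT	0/1
chr11	29220994	.	C	A	96.9	PASS	.	GT	0/1
chr11	29333404	.	A	T	47.4	PASS	.	GT	1/1
chr12	9044760	.	C	T	88.1	PASS	.	GT	0/1
chr12	21489876	.	G	T	60.4	PASS	.	GT	1/1
chr12	22650482	.	T	A	87.5	PASS	.	GT	1/1
chr13	4595968	.	C	A	46	PASS	.	GT	1/1
chr13	34399171	.	C	T	32.7	PASS	.	GT	0/1
chr16	33439745	.	C	A	66.3	PASS	.	GT	0/1
chr17	21282585	.	G	T	65.9	PASS	.	GT	1/1
chr17	29091251	.	T	G	68.1	PASS	.	GT	0/1
chr17	39855064	.	G	C	49	PASS	.	GT	0/1
chr18	29216052	.	A	G	51	PASS	.	GT	0/1
chr19	14781031	.	C	T	69	PASS	.	GT	0/1
chr19	36133139	.	A	T	86.7	PASS	.	GT	0/1
chr20	4562355	.	A	C	88.7	PASS	.	GT	0/1
chr20	8552071	.	C	A	83.4	PASS	.	GT	0/1
chr20	13313965	.	C	A	90.1	PASS	.	GT	0/1
chr21	12142617	.	C	T	46	PASS	.	GT	0/1
chr21	14891105	.	A	C	66.9	PASS	.	GT	0/1
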