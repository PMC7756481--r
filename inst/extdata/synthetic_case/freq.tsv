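chrom	pos	ref	alt	source	af
chr1	1131672	G	C	gnomad	0.2904
chr1	1131672	G	C	internal	0.2689
chr1	10557367	A	G	gnomad	2.725e-06
chr1	12881710	G	A	gnomad	0.1897
chr3	14633727	C	G	gnomad	0.1882
chr3	34578051	C	T	gnomad	0.1381
chr3	34578051	C	T	internal	0.1042
chr4	19082070	T	A	gnomad	0.1298
chr4	21787606	C	G	gnomad	0.0002758
chr5	9261183	A	C	gnomad	0.3603
chr5	13364237	T	A	gnomad	0.2646
chr5	13364237	T	A	internal	0.2231
chr5	17870607	T	G	gnomad	0.3074
chr5	36956684	A	G	gnomad	0.1997
chr6	29323542	T	G	gnomad	0.4414
chr6	30308288	A	T	gnomad	0.2258
chr6	30308288	A	T	internal	0.1615
chr6	32810587	G	C	gnomad	0.1051
chr7	27419541	G	T	gnomad	0.00021
chr8	13210337	G	C	gnomad	0.4169
chr8	29667101	T	G	gnomad	0.2572
chr8	29667101	T	G	internal	0.1903
chr8	31863787	C	T	gnomad	0.06469
chr8	31863787	C	T	internal	0.05023
chr9	3572055	T	C	gnomad	0.35
chr9	6193206	G	T	gnomad	0.2299
chr9	6193206	G	T	internal	0.207
chr9	18134983	C	G	gnomad	0.153
chr10	13926102	G	T	gnomad	0.1574
chr10	13926102	G	T	internal	0.1377
chr11	29220994	C	A	gnomad	0.2344
chr11	29333404	A	T	gnomad	0.4355
chr11	29333404	A	T	internal	0.4006
chr12	9044760	C	T	gnomad	0.3434
chr12	9044760	C	T	internal	0.3358
chr12	21489876	G	T	gnomad	0.09902
chr12	21489876	G	T	internal	0.09858
chr12	22650482	T	A	gnomad	0.3939
chr12	22650482	T	A	internal	0.381
chr13	4595968	C	A	gnomad	0.3702
chr13	4595968	C	A	internal	0.2012
chr13	34399171	C	T	gnomad	0.433
chr16	33439745	C	A	gnomad	0.2175
chr16	33439745	C	A	internal	0.2009
chr17	21282585	G	T	gnomad	0.3571
chr17	29091251	T	G	gnomad	0.2913
chr17	29091251	T	G	internal	0.2291
chr18	29216052	A	G	gnomad	0.2381
chr18	29216052	A	G	internal	0.2367
chr19	14781031	C	T	gnomad	2.123e-06
chr19	36133139	A	T	gnomad	0.473
chr19	36133139	A	T	internal	0.3556
chr20	4562355	A	C	gnomad	0.484
chr20	8552071	C	A	gnomad	0.2137
chr20	8552071	C	A	internal	0.196
chr20	13313965	C	A	gnomad	0.2294
chr21	12142617	C	T	gnomad	0.1757
chr21	12142617	C	T	internal	0.141
chr21	14891105	A	C	gnomad	0.4747
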