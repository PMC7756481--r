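chrom	pos	ref	alt	gene	consequence	hgvs_p	missense_meta	splice_ada	splice_rf	known_pathogenic_aa_match	in_hotspot_domain
chr1	1131672	G	C	GENE0011	intron_variant		NA	0.138	0.778	none	FALSE
chr1	10557367	A	G	GENE0003	missense_variant	p.Ala568Val	0.508	NA	NA	none	FALSE
chr1	12881710	G	A	GENE0010	inframe_indel		NA	NA	NA	none	FALSE
chr3	14633727	C	G	GENE0003	splice_acceptor_variant		NA	0.033	0.525	none	FALSE
chr3	34578051	C	T	GENE0004	synonymous_variant		NA	0.735	0.588	none	FALSE
chr4	19082070	T	A	GENE0016	missense_variant	p.Ala471Val	0.988	NA	NA	none	FALSE
chr4	21787606	C	G	GENE0001	synonymous_variant		NA	0.35	0.907	none	FALSE
chr5	9261183	A	C	NOGENE020	missense_variant	p.Ala384Val	0.47	NA	NA	none	FALSE
chr5	13364237	T	A	GENE0020	missense_variant	p.Ala238Val	0.036	NA	NA	none	FALSE
chr5	17870607	T	G	GENE0003	missense_variant	p.Ala208Val	0.395	NA	NA	none	FALSE
chr5	36956684	A	G	NOGENE039	intron_variant		NA	0.568	0.299	none	FALSE
chr6	29323542	T	G	GENE0010	missense_variant	p.Ala343Val	0.624	NA	NA	none	FALSE
chr6	30308288	A	T	GENE0020	synonymous_variant		NA	0.597	0.7	none	FALSE
chr6	32810587	G	C	NOGENE006	missense_variant	p.Ala188Val	0.657	NA	NA	none	FALSE
chr7	27419541	G	T	GENE0011	missense_variant	p.Ala342Val	0.498	NA	NA	none	FALSE
chr8	13210337	G	C	GENE0013	missense_variant	p.Ala738Val	0.328	NA	NA	none	FALSE
chr8	29667101	T	G	GENE0020	missense_variant	p.Ala702Val	0.964	NA	NA	none	FALSE
chr8	31863787	C	T	GENE0019	synonymous_variant		NA	0.944	0.739	none	FALSE
chr9	3572055	T	C	GENE0011	synonymous_variant		NA	0.632	0.872	none	FALSE
chr9	6193206	G	T	GENE0010	missense_variant	p.Ala407Val	0.14	NA	NA	none	FALSE
chr9	18134983	C	G	GENE0020	frameshift_variant		NA	NA	NA	none	FALSE
chr10	13926102	G	T	GENE0010	synonymous_variant		NA	0.211	0.774	none	FALSE
chr11	29220994	C	A	GENE0003	missense_variant	p.Ala195Val	0.296	NA	NA	none	FALSE
chr11	29333404	A	T	GENE0016	missense_variant	p.Ala605Val	0.545	NA	NA	none	FALSE
chr12	9044760	C	T	GENE0004	missense_variant	p.Ala761Val	0.093	NA	NA	none	FALSE
chr12	21489876	G	T	GENE0011	missense_variant	p.Ala277Val	0.765	NA	NA	none	FALSE
chr12	22650482	T	A	GENE0011	missense_variant	p.Ala83Val	0.392	NA	NA	none	FALSE
chr13	4595968	C	A	GENE0020	intron_variant		NA	0.206	0.525	none	FALSE
chr13	34399171	C	T	GENE0013	intron_variant		NA	0.409	0.943	none	FALSE
chr16	33439745	C	A	GENE0013	synonymous_variant		NA	0.996	0.218	none	FALSE
chr17	21282585	G	T	GENE0016	synonymous_variant		NA	0.448	0.808	none	FALSE
chr17	29091251	T	G	GENE0004	stop_lost		NA	NA	NA	none	FALSE
chr17	39855064	G	C	GENE0010	stop_gained	p.Arg123Ter	NA	NA	NA	none	FALSE
chr18	29216052	A	G	GENE0013	missense_variant	p.Ala53Val	0.992	NA	NA	none	FALSE
chr19	14781031	C	T	GENE0003	synonymous_variant		NA	0.188	0.032	none	FALSE
chr19	36133139	A	T	GENE0011	intron_variant		NA	0.99	0.499	none	FALSE
chr20	4562355	A	C	NOGENE031	intron_variant		NA	0.731	0.776	none	FALSE
chr20	8552071	C	A	GENE0003	missense_variant	p.Ala72Val	0.294	NA	NA	none	FALSE
chr20	13313965	C	A	GENE0004	synonymous_variant		NA	0.657	0.65	none	FALSE
chr21	12142617	C	T	GENE0013	intron_variant		NA	0.541	0.065	none	FALSE
chr21	14891105	A	C	GENE0010	missense_variant	p.Ala706Val	0.026	NA	NA	none	FALSE
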