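disease_id	name	inheritance	mechanism	missense_constrained	max_credible_af
DIS:0001	synthetic disease 1	AD	LoF	FALSE	2e-04
DIS:0002	synthetic disease 2	AR	LoF	TRUE	0.002
DIS:0003	synthetic disease 3	AR	unknown	TRUE	0.002
DIS:0004	synthetic disease 4	AD	LoF	FALSE	2e-04
DIS:0005	synthetic disease 5	XL	unknown	FALSE	2e-04
DIS:0006	synthetic disease 6	AR	LoF	FALSE	0.002
DIS:0007	synthetic disease 7	AD	LoF	TRUE	2e-04
DIS:0008	synthetic disease 8	AD	GoF	TRUE	2e-04
DIS:0009	synthetic disease 9	AD	LoF	TRUE	2e-04
DIS:0010	synthetic disease 10	AD	LoF	FALSE	2e-04
DIS:0011	synthetic disease 11	AR	LoF	FALSE	0.002
DIS:0012	synthetic disease 12	AD	LoF	FALSE	2e-04
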