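gene	disease_id
GENE0020	DIS:0001
GENE0003	DIS:0002
GENE0019	DIS:0003
GENE0010	DIS:0004
GENE0013	DIS:0005
GENE0013	DIS:0006
GENE0001	DIS:0007
GENE0016	DIS:0008
GENE0004	DIS:0009
GENE0001	DIS:0010
GENE0003	DIS:0011
GENE0011	DIS:0012
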