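disease_id	term
DIS:0001	HP:0000006
DIS:0001	HP:0000018
DIS:0001	HP:0000012
DIS:0002	HP:0000040
DIS:0002	HP:0000028
DIS:0002	HP:0000018
DIS:0003	HP:0000009
DIS:0003	HP:0000038
DIS:0003	HP:0000026
DIS:0004	HP:0000037
DIS:0004	HP:0000032
DIS:0004	HP:0000019
DIS:0004	HP:0000008
DIS:0005	HP:0000027
DIS:0005	HP:0000030
DIS:0005	HP:0000006
DIS:0005	HP:0000032
DIS:0005	HP:0000005
DIS:0006	HP:0000006
DIS:0006	HP:0000010
DIS:0006	HP:0000017
DIS:0006	HP:0000035
DIS:0007	HP:0000031
DIS:0007	HP:0000018
DIS:0007	HP:0000038
DIS:0007	HP:0000028
DIS:0008	HP:0000032
DIS:0008	HP:0000010
DIS:0008	HP:0000013
DIS:0009	HP:0000018
DIS:0009	HP:0000011
DIS:0009	HP:0000006
DIS:0010	HP:0000036
DIS:0010	HP:0000028
DIS:0010	HP:0000015
DIS:0010	HP:0000030
DIS:0010	HP:0000022
DIS:0011	HP:0000014
DIS:0011	HP:0000013
DIS:0011	HP:0000024
DIS:0011	HP:0000029
DIS:0011	HP:0000035
DIS:0012	HP:0000027
DIS:0012	HP:0000030
DIS:0012	HP:0000005
DIS:0012	HP:0000014
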