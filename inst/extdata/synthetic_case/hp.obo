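format-version: 1.2

[Term]
id: HP:0000001
name: synthetic phenotype root

[Term]
id: HP:0000002
name: synthetic term 2 (level 1)
is_a: HP:0000001

[Term]
id: HP:0000003
name: synthetic term 3 (level 1)
is_a: HP:0000001

[Term]
id: HP:0000004
name: synthetic term 4 (level 1)
is_a: HP:0000001

[Term]
id: HP:0000005
name: synthetic term 5 (level 2)
is_a: HP:0000002

[Term]
id: HP:0000006
name: synthetic term 6 (level 2)
is_a: HP:0000002

[Term]
id: HP:0000007
name: synthetic term 7 (level 2)
is_a: HP:0000002

[Term]
id: HP:0000008
name: synthetic term 8 (level 2)
is_a: HP:0000003

[Term]
id: HP:0000009
name: synthetic term 9 (level 2)
is_a: HP:0000003

[Term]
id: HP:0000010
name: synthetic term 10 (level 2)
is_a: HP:0000003

[Term]
id: HP:0000011
name: synthetic term 11 (level 2)
is_a: HP:0000004

[Term]
id: HP:0000012
name: synthetic term 12 (level 2)
is_a: HP:0000004

[Term]
id: HP:0000013
name: synthetic term 13 (level 2)
is_a: HP:0000004
is_a: HP:0000003

[Term]
id: HP:0000014
name: synthetic term 14 (level 3)
is_a: HP:0000005

[Term]
id: HP:0000015
name: synthetic term 15 (level 3)
is_a: HP:0000005

[Term]
id: HP:0000016
name: synthetic term 16 (level 3)
is_a: HP:0000005

[Term]
id: HP:0000017
name: synthetic term 17 (level 3)
is_a: HP:0000006

[Term]
id: HP:0000018
name: synthetic term 18 (level 3)
is_a: HP:0000006
is_a: HP:0000005

[Term]
id: HP:0000019
name: synthetic term 19 (level 3)
is_a: HP:0000006

[Term]
id: HP:0000020
name: synthetic term 20 (level 3)
is_a: HP:0000007
is_a: HP:0000011

[Term]
id: HP:0000021
name: synthetic term 21 (level 3)
is_a: HP:0000007

[Term]
id: HP:0000022
name: synthetic term 22 (level 3)
is_a: HP:0000007

[Term]
id: HP:0000023
name: synthetic term 23 (level 3)
is_a: HP:0000008

[Term]
id: HP:0000024
name: synthetic term 24 (level 3)
is_a: HP:0000008

[Term]
id: HP:0000025
name: synthetic term 25 (level 3)
is_a: HP:0000008

[Term]
id: HP:0000026
name: synthetic term 26 (level 3)
is_a: HP:0000009

[Term]
id: HP:0000027
name: synthetic term 27 (level 3)
is_a: HP:0000009

[Term]
id: HP:0000028
name: synthetic term 28 (level 3)
is_a: HP:0000009

[Term]
id: HP:0000029
name: synthetic term 29 (level 3)
is_a: HP:0000010
is_a: HP:0000004

[Term]
id: HP:0000030
name: synthetic term 30 (level 3)
is_a: HP:0000010

[Term]
id: HP:0000031
name: synthetic term 31 (level 3)
is_a: HP:0000010

[Term]
id: HP:0000032
name: synthetic term 32 (level 3)
is_a: HP:0000011

[Term]
id: HP:0000033
name: synthetic term 33 (level 3)
is_a: HP:0000011
is_a: HP:0000002

[Term]
id: HP:0000034
name: synthetic term 34 (level 3)
is_a: HP:0000011

[Term]
id: HP:0000035
name: synthetic term 35 (level 3)
is_a: HP:0000012

[Term]
id: HP:0000036
name: synthetic term 36 (level 3)
is_a: HP:0000012

[Term]
id: HP:0000037
name: synthetic term 37 (level 3)
is_a: HP:0000012

[Term]
id: HP:0000038
name: synthetic term 38 (level 3)
is_a: HP:0000013

[Term]
id: HP:0000039
name: synthetic term 39 (level 3)
is_a: HP:0000013

[Term]
id: HP:0000040
name: synthetic term 40 (level 3)
is_a: HP:0000013

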