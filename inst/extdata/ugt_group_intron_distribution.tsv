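group	introns_0	introns_1	introns_2	introns_3	introns_8
A	13	4	0	0	0
B	3	0	0	0	0
C	1	0	0	0	0
D	15	1	1	0	1
E	22	3	0	0	0
F	1	1	0	0	0
G	0	8	1	0	0
H	0	14	2	1	0
I	0	14	1	2	0
J	0	2	1	0	0
K	0	2	0	0	0
L	4	6	2	0	0
M	6	1	0	0	0
N	0	1	0	0	0
O	4	0	0	0	0
P	1	6	0	0	0
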