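site	colonies	library
R	7	SAL_1
S	5	SAL_1
T	8	SAL_1
U	9	SAL_1
V	9	SAL_1
W	8	SAL_1
A	8	SAL_2
B	9	SAL_2
C	9	SAL_2
D	7	SAL_2
E	9	SAL_2
F	7	SAL_2
X	1	SAL_2
Y	3	SAL_2
G	9	SAL_3
H	6	SAL_3
N	5	SAL_3
O	7	SAL_3
P	9	SAL_3
Q	8	SAL_3
I	9	SAL_4
J	8	SAL_4
K	9	SAL_4
L	5	SAL_4
M	8	SAL_4
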