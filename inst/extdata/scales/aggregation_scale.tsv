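residue	value
A	0.2
C	0.6
D	-1.2
E	-1.2
F	1.2
G	-0.2
H	-0.3
I	1.4
K	-1.5
L	1.2
M	0.8
N	-0.5
P	-1.0
Q	-0.5
R	-1.4
S	-0.3
T	0.0
V	1.3
W	0.9
Y	0.8
X	0.0
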