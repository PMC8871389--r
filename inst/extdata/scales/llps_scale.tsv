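residue	value
A	-0.2
C	-0.4
D	0.0
E	0.1
F	0.6
G	0.8
H	0.3
I	-0.8
K	0.2
L	-0.8
M	-0.3
N	0.5
P	0.5
Q	0.6
R	0.9
S	0.6
T	0.1
V	-0.7
W	0.4
Y	0.9
X	0.0
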