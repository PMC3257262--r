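aa	j_hz
A	6.6
C	7.2
D	7.2
E	7.0
F	7.3
G	6.9
H	7.3
I	7.5
K	7.0
L	7.0
M	7.1
N	7.2
P	NA
Q	7.1
R	7.1
S	7.1
T	7.4
V	7.5
W	7.2
Y	7.3
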