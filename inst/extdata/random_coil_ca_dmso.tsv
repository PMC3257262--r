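aa	shift_ppm	medium
A	50.6	dmso
C	56.4	dmso
D	52.3	dmso
E	54.8	dmso
F	56.1	dmso
G	43.4	dmso
H	53.9	dmso
I	59.9	dmso
K	54.9	dmso
L	53.8	dmso
M	54.0	dmso
N	51.2	dmso
P	61.2	dmso
Q	54.4	dmso
R	54.7	dmso
S	56.7	dmso
T	60.2	dmso
V	60.9	dmso
W	55.8	dmso
Y	56.3	dmso
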