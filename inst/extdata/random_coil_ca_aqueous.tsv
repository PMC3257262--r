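aa	shift_ppm	medium
A	52.5	aqueous
C	58.3	aqueous
D	54.1	aqueous
E	56.7	aqueous
F	57.9	aqueous
G	45.0	aqueous
H	55.8	aqueous
I	61.6	aqueous
K	56.7	aqueous
L	55.6	aqueous
M	55.9	aqueous
N	53.0	aqueous
P	63.0	aqueous
Q	56.2	aqueous
R	56.5	aqueous
S	58.5	aqueous
T	62.0	aqueous
V	62.6	aqueous
W	57.6	aqueous
Y	58.1	aqueous
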