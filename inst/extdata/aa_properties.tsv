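# Canonical amino-acid property table (version 1).
# code: one-letter symbol
# h: Kyte-Doolittle hydropathy (positive = hydrophobic)
# pka_side: side-chain pKa, NA when the side chain does not titrate
# charge_sign: +1 base (protonated form charged), -1 acid (deprotonated form charged), 0 neutral
code	h	pka_side	charge_sign
A	1.8	NA	0
R	-4.5	12.5	1
N	-3.5	NA	0
D	-3.5	3.9	-1
C	2.5	8.4	-1
Q	-3.5	NA	0
E	-3.5	4.1	-1
G	-0.4	NA	0
H	-3.2	6.0	1
I	4.5	NA	0
L	3.8	NA	0
K	-3.9	10.5	1
M	1.9	NA	0
F	2.8	NA	0
P	-1.6	NA	0
S	-0.8	NA	0
T	-0.7	NA	0
W	-0.9	NA	0
Y	-1.3	10.5	-1
V	4.2	NA	0
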