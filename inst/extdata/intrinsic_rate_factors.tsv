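# Nearest-neighbour side-chain correction factors (log10) for intrinsic
# backbone amide hydrogen-exchange rates, relative to the poly-DL-alanine
# reference, in the style of Bai, Milne, Mayne & Englander (1993)
# Proteins 17:75-86, as propagated by the community spreadsheet/SPHERE
# implementations (values reproduced to two decimals from those sources).
# Convention: the amide NH of residue i receives the L (left) factor of
# residue i's own side chain and the R (right) factor of residue i-1's
# side chain: log k_A(i) = log k_A,ref + acid_L(aa_i) + acid_R(aa_i-1),
# and likewise for base catalysis. Row NT is the N-terminal ammonium
# group (applies its R factor to the amide of residue 2); row CT is the
# C-terminal carboxylate (applies its L factor to the last amide).
# D and E are the ionized (carboxylate) forms appropriate near neutral
# pD; Dh/Eh are the protonated forms; H is the protonated imidazolium.
# res	acid_L	acid_R	base_L	base_R
A	0.00	0.00	0.00	0.00
R	-0.59	-0.32	0.08	0.22
N	-0.58	-0.13	0.49	0.32
D	0.90	0.58	0.10	-0.18
Dh	-0.90	-0.12	0.69	0.60
C	-0.54	-0.46	0.62	0.55
E	-0.90	0.31	-0.11	-0.15
Eh	-0.60	-0.27	0.24	0.39
Q	-0.47	-0.27	0.06	0.20
G	-0.22	0.22	0.27	0.17
H	-0.80	-0.51	0.80	0.83
I	-0.91	-0.59	-0.73	-0.23
L	-0.57	-0.13	-0.58	-0.21
K	-0.56	-0.29	-0.04	0.12
M	-0.64	-0.28	-0.01	0.11
F	-0.52	-0.43	-0.24	0.06
P	0.00	-0.19	0.00	-0.24
S	-0.44	-0.39	0.37	0.30
T	-0.79	-0.47	-0.07	0.20
W	-0.40	-0.44	-0.41	-0.11
Y	-0.41	-0.37	-0.27	0.05
V	-0.74	-0.30	-0.70	-0.14
NT	0.00	-1.32	0.00	1.62
CT	0.96	0.00	-1.80	0.00
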