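# nearest-neighbor parameter table (kcal/mol)
STACK
CG/CG	-1.17
GC/CG	-1.13
AU/CG	-2.43
UA/CG	-1.34
GU/CG	-1.72
UG/CG	-1.96
CG/GC	-1.53
GC/GC	-2.73
AU/GC	-1.69
UA/GC	-1.59
GU/GC	-2.08
UG/GC	-1.56
CG/AU	-1.13
GC/AU	-2.49
AU/AU	-2.08
UA/AU	-1.12
GU/AU	-1.04
UG/AU	-2.77
CG/UA	-2.05
GC/UA	-1.88
AU/UA	-1.19
UA/UA	-2.72
GU/UA	-1.02
UG/UA	-1.11
CG/GU	-2.84
GC/GU	-1.97
AU/GU	-2.22
UA/GU	-1.19
GU/GU	-2.11
UG/GU	-1.33
CG/UG	-1.52
GC/UG	-1.38
AU/UG	-2.22
UA/UG	-1.63
GU/UG	-2.99
UG/UG	-1.33
HAIRPIN_LEN
3	4
4	4.61
5	5.35
6	5.52
7	5.67
8	5.93
9	5.94
10	6.59
11	6.49
12	6.9
13	7.01
14	7.02
15	7.3
16	7.24
17	7.2
18	7.31
19	7.43
20	7.71
21	7.42
22	7.86
23	7.9
24	7.72
25	7.84
26	8.04
27	8.18
28	8.4
29	8.35
30	8.31
INTERIOR_LEN
1	1.92
2	2.81
3	3.56
4	4.34
5	4.66
6	4.76
7	4.93
8	5.21
9	5.45
10	5.77
11	5.8
12	6.21
13	5.99
14	6.31
15	6.5
16	6.35
17	6.75
18	6.64
19	6.83
20	7.07
21	7.22
22	7.19
23	7.1
24	7.11
25	7.18
26	7.35
27	7.6
28	7.33
29	7.5
MULTILOOP
alpha	3.4
beta	0.4
gamma	0
INIT
init	4.09
PASSTHROUGH
dangle5_A	-0.13
dangle5_C	-0.13
dangle5_G	-0.21
dangle5_U	-0.37
coax_flush	-2.1
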