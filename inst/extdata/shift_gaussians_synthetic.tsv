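amino_acid	atom_type	c_mean	c_sd	h_mean	h_sd
A	CA-HA	53.1	1.9	4.26	0.44
A	CB-HB	19.0	1.8	1.35	0.26
R	CA-HA	56.8	2.3	4.30	0.46
R	CB-HB	30.7	1.8	1.79	0.27
R	CG-HG	27.2	1.2	1.57	0.27
R	CD-HD	43.2	0.9	3.12	0.24
N	CA-HA	53.5	1.9	4.67	0.36
N	CB-HB	38.7	1.7	2.81	0.31
D	CA-HA	54.7	2.0	4.59	0.32
D	CB-HB	40.9	1.6	2.72	0.27
C	CA-HA	58.2	3.3	4.69	0.54
C	CB-HB	32.8	5.5	2.95	0.45
Q	CA-HA	56.6	2.2	4.27	0.44
Q	CB-HB	29.2	1.9	2.05	0.25
Q	CG-HG	33.8	1.1	2.32	0.27
E	CA-HA	57.3	2.1	4.25	0.41
E	CB-HB	30.0	1.7	2.03	0.21
E	CG-HG	36.1	1.2	2.28	0.21
G	CA-HA	45.4	1.3	3.96	0.37
H	CA-HA	56.5	2.3	4.61	0.44
H	CB-HB	30.2	2.1	3.10	0.35
I	CA-HA	61.6	2.7	4.17	0.57
I	CB-HB	38.6	2.0	1.79	0.29
I	CG1-HG1	27.7	1.7	1.27	0.40
I	CG2-HG2	17.5	1.4	0.91	0.27
I	CD1-HD1	13.4	1.7	0.86	0.29
L	CA-HA	55.6	2.1	4.32	0.47
L	CB-HB	42.3	1.9	1.62	0.34
L	CG-HG	26.8	1.1	1.51	0.33
L	CD1-HD1	24.7	1.6	0.85	0.27
L	CD2-HD2	24.1	1.7	0.83	0.29
K	CA-HA	56.9	2.2	4.26	0.44
K	CB-HB	32.8	1.8	1.78	0.25
K	CG-HG	24.9	1.1	1.37	0.26
K	CD-HD	28.9	1.1	1.61	0.22
K	CE-HE	41.9	0.8	2.93	0.19
M	CA-HA	56.1	2.2	4.41	0.48
M	CB-HB	33.0	2.2	2.03	0.34
M	CG-HG	32.0	1.2	2.43	0.35
M	CE-HE	17.1	1.5	1.89	0.41
F	CA-HA	58.1	2.6	4.61	0.57
F	CB-HB	39.9	2.1	2.99	0.37
P	CA-HA	63.3	1.5	4.40	0.33
P	CB-HB	31.8	1.2	2.07	0.34
P	CG-HG	27.2	1.1	1.92	0.31
P	CD-HD	50.3	1.0	3.64	0.35
S	CA-HA	58.7	2.1	4.50	0.40
S	CB-HB	63.8	1.5	3.87	0.27
T	CA-HA	62.2	2.6	4.45	0.48
T	CB-HB	69.6	1.7	4.16	0.33
T	CG2-HG2	21.5	1.1	1.14	0.22
W	CA-HA	57.7	2.6	4.70	0.52
W	CB-HB	30.0	2.0	3.19	0.36
Y	CA-HA	58.1	2.5	4.62	0.55
Y	CB-HB	38.8	2.2	2.90	0.37
V	CA-HA	62.5	2.9	4.17	0.58
V	CB-HB	32.7	1.8	1.98	0.32
V	CG1-HG1	21.4	1.4	0.83	0.27
V	CG2-HG2	21.3	1.6	0.82	0.29
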