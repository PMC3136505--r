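property	description	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
pK'	Equilibrium constant (ionization of COOH)	2.34	1.96	1.88	2.19	1.83	2.34	1.82	2.36	2.18	2.36	2.28	2.02	1.99	2.17	2.17	2.21	2.09	2.32	2.38	2.2
Ra	Solvent accessible reduction ratio	0.74	0.91	0.62	0.62	0.88	0.72	0.78	0.88	0.52	0.85	0.85	0.63	0.64	0.62	0.64	0.66	0.7	0.86	0.85	0.76
an	Power to be at the N-terminal	0.7	0.65	1.52	0.9	0.6	1.67	0.87	0.35	0.73	0.55	0.6	1.7	1.6	0.75	0.65	1.5	1.2	0.5	0.73	0.75
Hp	Surrounding hydrophobicity	12.97	14.63	10.85	11.89	14	12.43	12.16	15.67	11.36	14.9	14.39	11.42	11.37	11.76	11.72	11.23	11.69	15.71	13.93	13.42
H	Hydropathy	1.8	2.5	-3.5	-3.5	2.8	-0.4	-3.2	4.5	-3.9	3.8	1.9	-3.5	-1.6	-3.5	-4.5	-0.8	-0.7	4.2	-0.9	-1.3
Ko	Compressibility	-25.5	-32.8	-33.1	-36.2	-34.5	-27	-31.8	-31.8	-32.4	-31.8	-31.2	-30.9	-23.3	-32.6	-26.6	-29.9	-31.2	-30.9	-30.2	-35
F	Mean r.m.s. fluctuation displacement	0.25	0.21	0.36	0.42	0.22	0.36	0.27	0.22	0.48	0.21	0.26	0.37	0.33	0.42	0.38	0.34	0.3	0.22	0.2	0.23
Ht	Thermodynamic transfer hydrophobicity	0.87	1.52	0.66	0.67	2.87	0.1	0.87	3.15	1.64	2.17	1.67	0.09	2.77	0	0.85	0.07	0.07	1.87	3.77	2.67
P	Polarity	8.1	5.5	13	12.3	5.2	9	10.4	5.2	11.3	4.9	5.7	11.6	8	10.5	10.5	9.2	8.6	5.9	5.4	6.2
c	Composition	0	2.75	1.38	0.92	0	0.74	0.58	0	0.33	0	0	1.33	0.39	0.89	0.65	1.42	0.71	0	0.13	0.2
Mv	Molecular volume	31	55	54	83	132	3	96	111	119	111	105	56	32.5	85	124	32	61	84	170	136
pHi	Isoelectric point	6	5.07	2.77	3.22	5.48	5.97	7.59	6.02	9.74	5.98	5.74	5.41	6.3	5.65	10.76	5.68	5.6	5.96	5.89	5.66
Bl	Bulkiness	11.5	13.46	11.68	13.57	19.8	3.4	13.69	21.4	15.71	21.4	16.25	12.82	17.43	14.45	14.28	9.47	15.77	21.57	21.67	18.03
Br	Buriedness	0.38	0.45	0.15	0.18	0.5	0.36	0.17	0.6	0.03	0.45	0.4	0.12	0.18	0.07	0.01	0.22	0.23	0.54	0.27	0.15
Pa	Alpha-helical tendency	1.42	0.7	1.01	1.51	1.13	0.57	1	1.08	1.16	1.21	1.45	0.67	0.57	1.11	0.98	0.77	0.83	1.06	1.08	0.69
Pb	Beta-sheet tendency	0.83	1.19	0.54	0.37	1.38	0.75	0.87	1.6	0.74	1.3	1.05	0.89	0.55	1.1	0.93	0.75	1.19	1.7	1.37	1.47
Pt	Reverse turn tendency	0.66	1.19	1.46	0.74	0.6	1.56	0.95	0.47	1.01	0.59	0.6	1.56	1.52	0.98	0.95	1.43	0.96	0.5	0.96	1.14
Hnc	Normalized consensus hydrophobicity	0.62	0.29	-0.9	-0.74	1.19	0.48	-0.4	1.38	-1.5	1.06	0.64	-0.78	0.12	-0.85	-2.53	-0.18	-0.05	1.08	0.81	0.26
Mr	Molar refractivity	4.34	35.77	12	17.26	29.4	0	21.81	19.06	21.29	18.78	21.64	13.28	10.93	17.56	26.66	6.35	11.01	13.92	42.53	31.53
Et	Total non-bonded energy	-0.91	-1.05	-0.69	-0.7	-1.1	-0.67	-0.91	-1.08	-0.7	-1.07	-1.05	-0.6	-0.86	-0.71	-0.93	-0.75	-0.82	-1.06	-1.14	-1
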