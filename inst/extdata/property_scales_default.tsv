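aa	hydrophobicity	hydrophilicity	mass	pK1	pK2	pI	rigidity	flexibility	irreplaceability
A	1.8	-0.5	71.08	2.34	9.69	6.00	1.42	0.357	-100
C	2.5	-1.0	103.14	1.96	10.28	5.07	0.70	0.346	-20
D	-3.5	3.0	115.09	1.88	9.60	2.77	1.01	0.511	-106
E	-3.5	3.0	129.12	2.19	9.67	3.22	1.51	0.497	-102
F	2.8	-2.5	147.18	1.83	9.13	5.48	1.13	0.314	-41
G	-0.4	0.0	57.05	2.34	9.60	5.97	0.57	0.544	-49
H	-3.2	-0.5	137.14	1.82	9.17	7.59	1.00	0.323	-66
I	4.5	-1.8	113.16	2.36	9.60	6.02	1.08	0.462	-96
K	-3.9	3.0	128.17	2.18	8.95	9.74	1.16	0.466	-56
L	3.8	-1.8	113.16	2.36	9.60	5.98	1.21	0.365	-40
M	1.9	-1.3	131.19	2.28	9.21	5.74	1.45	0.295	-94
N	-3.5	0.2	114.10	2.02	8.80	5.41	0.67	0.463	-134
P	-1.6	0.0	97.12	1.99	10.96	6.30	0.57	0.509	-56
Q	-3.5	0.2	128.13	2.17	9.13	5.65	1.11	0.493	-93
R	-4.5	3.0	156.19	2.17	9.04	10.76	0.98	0.529	-65
S	-0.8	0.3	87.08	2.21	9.15	5.68	0.77	0.507	-120
T	-0.7	-0.4	101.10	2.11	9.62	5.60	0.83	0.444	-97
V	4.2	-1.5	99.13	2.32	9.62	5.96	1.06	0.386	-74
W	-0.9	-3.4	186.21	2.38	9.39	5.89	1.08	0.305	-18
Y	-1.3	-2.3	163.18	2.20	9.11	5.66	0.69	0.420	-41
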