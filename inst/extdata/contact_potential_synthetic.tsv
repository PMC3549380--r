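RES	ALA	ARG	ASN	ASP	CYS	GLN	GLU	GLY	HIS	ILE	LEU	LYS	MET	PHE	PRO	SER	THR	TRP	TYR	VAL
ALA	-0.13	-0.01	0.05	0.06	-0.4	0.03	0.05	-0.03	-0.1	-0.5	-0.46	0.13	-0.51	-0.52	0.03	0.01	-0.04	-0.37	-0.19	-0.37
ARG	-0.01	0.58	0.13	-0.35	-0.22	0.12	-0.35	0.07	0.26	-0.3	-0.27	0.69	-0.31	-0.31	0.12	0.1	0.07	-0.2	-0.05	-0.2
ASN	0.05	0.13	0.17	0.18	-0.15	0.16	0.17	0.11	0.06	-0.21	-0.19	0.22	-0.22	-0.23	0.16	0.14	0.11	-0.13	0.01	-0.12
ASP	0.06	-0.35	0.18	0.68	-0.13	0.17	0.67	0.12	-0.17	-0.19	-0.17	-0.26	-0.2	-0.21	0.17	0.15	0.12	-0.11	0.02	-0.1
CYS	-0.4	-0.22	-0.15	-0.13	-0.82	-0.17	-0.14	-0.27	-0.37	-0.96	-0.9	-0.02	-0.98	-0.99	-0.17	-0.21	-0.27	-0.77	-0.49	-0.77
GLN	0.03	0.12	0.16	0.17	-0.17	0.14	0.16	0.1	0.05	-0.24	-0.21	0.22	-0.25	-0.26	0.14	0.13	0.1	-0.15	-0.01	-0.15
GLU	0.05	-0.35	0.17	0.67	-0.14	0.16	0.67	0.12	-0.17	-0.2	-0.18	-0.26	-0.21	-0.22	0.16	0.14	0.12	-0.12	0.01	-0.11
GLY	-0.03	0.07	0.11	0.12	-0.27	0.1	0.12	0.04	-0.01	-0.35	-0.32	0.18	-0.36	-0.37	0.1	0.08	0.04	-0.24	-0.08	-0.24
HIS	-0.1	0.26	0.06	-0.17	-0.37	0.05	-0.17	-0.01	0.05	-0.46	-0.42	0.39	-0.47	-0.48	0.05	0.03	-0.01	-0.34	-0.16	-0.34
ILE	-0.5	-0.3	-0.21	-0.19	-0.96	-0.24	-0.2	-0.35	-0.46	-1.12	-1.05	-0.08	-1.14	-1.15	-0.24	-0.28	-0.35	-0.91	-0.6	-0.91
LEU	-0.46	-0.27	-0.19	-0.17	-0.9	-0.21	-0.18	-0.32	-0.42	-1.05	-0.99	-0.06	-1.08	-1.09	-0.21	-0.25	-0.32	-0.86	-0.56	-0.85
LYS	0.13	0.69	0.22	-0.26	-0.02	0.22	-0.26	0.18	0.39	-0.08	-0.06	0.76	-0.08	-0.09	0.22	0.2	0.18	-0.01	0.1	-0.01
MET	-0.51	-0.31	-0.22	-0.2	-0.98	-0.25	-0.21	-0.36	-0.47	-1.14	-1.08	-0.08	-1.16	-1.18	-0.25	-0.29	-0.36	-0.93	-0.61	-0.92
PHE	-0.52	-0.31	-0.23	-0.21	-0.99	-0.26	-0.22	-0.37	-0.48	-1.15	-1.09	-0.09	-1.18	-1.19	-0.26	-0.3	-0.37	-0.94	-0.62	-0.94
PRO	0.03	0.12	0.16	0.17	-0.17	0.14	0.16	0.1	0.05	-0.24	-0.21	0.22	-0.25	-0.26	0.14	0.13	0.1	-0.15	-0.01	-0.15
SER	0.01	0.1	0.14	0.15	-0.21	0.13	0.14	0.08	0.03	-0.28	-0.25	0.2	-0.29	-0.3	0.13	0.11	0.08	-0.18	-0.04	-0.18
THR	-0.04	0.07	0.11	0.12	-0.27	0.1	0.12	0.04	-0.01	-0.35	-0.32	0.18	-0.36	-0.37	0.1	0.08	0.04	-0.25	-0.09	-0.24
TRP	-0.37	-0.2	-0.13	-0.11	-0.77	-0.15	-0.12	-0.24	-0.34	-0.91	-0.86	-0.01	-0.93	-0.94	-0.15	-0.18	-0.25	-0.73	-0.46	-0.73
TYR	-0.19	-0.05	0.01	0.02	-0.49	-0.01	0.01	-0.08	-0.16	-0.6	-0.56	0.1	-0.61	-0.62	-0.01	-0.04	-0.09	-0.46	-0.25	-0.46
VAL	-0.37	-0.2	-0.12	-0.1	-0.77	-0.15	-0.11	-0.24	-0.34	-0.91	-0.85	-0.01	-0.92	-0.94	-0.15	-0.18	-0.24	-0.73	-0.46	-0.72
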