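gene	panel	count_E	count_M	pct_printed_E	pct_printed_M	fold_printed	direction
FADS2	spheroid	147	55	48	31	1.6	E_over_M
CTSV	spheroid	41	9	13	5	2.7	E_over_M
S100B	spheroid	61	3	20	2	12.0	E_over_M
SCG2	spheroid	2	0	1	0	1.0	E_over_M
BAMBI	spheroid	58	28	19	16	1.2	E_over_M
DUSP6	spheroid	64	23	21	13	1.6	E_over_M
LCP1	spheroid	13	3	4	2	2.6	E_over_M
RBBP7	spheroid	168	63	55	35	1.6	E_over_M
QPCT	spheroid	27	22	9	12	0.7	E_over_M
SOX2	spheroid	52	10	17	6	3.1	E_over_M
THY1	spheroid	44	3	14	2	8.7	E_over_M
ZEB1	spheroid	4	2	1	1	1.2	E_over_M
BMI1	spheroid	17	6	6	3	1.7	E_over_M
CD24	spheroid	141	78	46	43	1.1	E_over_M
NANOG	spheroid	8	11	3	6	0.4	E_over_M
MYC	spheroid	118	39	39	22	1.8	E_over_M
PROM1	spheroid	5	14	2	8	0.2	E_over_M
RAB33A	spheroid	22	3	7	2	4.3	E_over_M
GNG2	spheroid	19	1	6	1	11.2	E_over_M
ACSL3	spheroid	31	14	10	8	1.3	E_over_M
HMGCS1	spheroid	38	17	12	9	1.3	E_over_M
FXYD6	spheroid	32	4	10	2	4.7	E_over_M
MLF1	spheroid	19	2	6	1	5.6	E_over_M
ZRSR2	spheroid	35	10	11	6	2.1	E_over_M
PTH1R	spheroid	1	0	0	0	0.0	E_over_M
S100A1	spheroid	8	5	3	3	0.9	E_over_M
MVK	spheroid	20	5	7	3	2.4	E_over_M
TMIE	spheroid	0	0	0	0	0.0	E_over_M
SERPINF1	spheroid	45	16	15	9	1.7	E_over_M
THOC6	spheroid	85	29	28	16	1.7	E_over_M
GNS	spheroid	42	24	14	13	1.0	E_over_M
CHAC1	spheroid	72	24	24	13	1.8	E_over_M
CLGN	spheroid	46	5	15	3	5.4	E_over_M
KIF1A	spheroid	42	3	14	2	8.3	E_over_M
BTG1	spheroid	205	95	67	53	1.3	E_over_M
SOD3	spheroid	14	7	5	4	1.2	E_over_M
RMND5B	spheroid	29	15	10	8	1.1	E_over_M
ZCCHC3	spheroid	53	10	17	6	3.1	E_over_M
SFN	serum	5	18	2	10	6.1	M_over_E
ANKRD1	serum	15	37	5	21	4.2	M_over_E
KRTAP2-3	serum	1	1	0	1	1.7	M_over_E
CA2	serum	0	0	0	0	0.0	M_over_E
CPA4	serum	4	1	1	1	0.4	M_over_E
EPHB3	serum	1	2	0	1	3.4	M_over_E
PLEK2	serum	8	2	3	1	0.4	M_over_E
IGFBP3	serum	2	1	1	1	0.8	M_over_E
DMKN	serum	62	43	20	24	1.2	M_over_E
CAPG	serum	51	34	17	19	1.1	M_over_E
TAGLN	serum	11	2	4	1	0.3	M_over_E
FXYD5	serum	21	6	7	3	0.5	M_over_E
KRT19	serum	76	79	25	44	1.8	M_over_E
ID4	serum	73	51	24	28	1.2	M_over_E
ARL4C	serum	23	23	8	13	1.7	M_over_E
PFKP	serum	19	15	6	8	1.3	M_over_E
MT1L	serum	18	6	6	3	0.6	M_over_E
ALDH1A1	serum	24	14	8	8	1.0	M_over_E
VPS13D	serum	4	4	1	2	1.7	M_over_E
ID1	serum	2	0	1	0	0.0	M_over_E
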