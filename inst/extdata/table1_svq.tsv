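accession	gene	functional_group	reg_p7	p_p7	reg_p637	p_p637	svq	h	score	qm	mw_da	pi
P08461	Dlat	carbohydrate_metabolism	-	NA	up	0.0062	0.32	5	241	28	67637	8.76
P04764	Eno1	carbohydrate_metabolism	down	0.1745	-	NA	1.90	5	107	12	47440	6.16
P07323	Eno2	carbohydrate_metabolism	down	0.3367	-	NA	2.22	6	272	32	47510	5.03
P04797	Gapdh	carbohydrate_metabolism	down	0.0250	-	NA	3.09	6	262	34	36090	8.14
P04636	Mdh2	carbohydrate_metabolism	-	NA	up	0.1441	0.49	5	242	24	36117	8.93
Q5XI78	Ogdh	carbohydrate_metabolism	down	0.0190	-	NA	1.93	4	158	18	117419	6.3
P49432	Pdhb	carbohydrate_metabolism	down	0.0039	-	NA	5.80	6	139	18	39299	6.2
D3Z955	Pgm2l1	carbohydrate_metabolism	up	0.0250	-	NA	0.52	6	126	17	71102	6.09
P50137	Tkt	carbohydrate_metabolism	down	0.0065	-	NA	2.09	6	339	35	68342	7.23
Q6Q0N1	Cndp2	amino_acid_metabolism	-	NA	up	0.0106	0.48	5	205	29	53116	5.43
Q4V7C6	Gmps	amino_acid_metabolism	up	0.0062	-	NA	0.52	5	130	17	77507	6.21
P14882	Pcca	amino_acid_metabolism	down	0.0283	-	NA	2.14	5	262	32	82198	7.59
Q5XI22	Acat2	fat_metabolism	-	NA	up	0.0209	0.42	4	180	16	41538	6.86
O35263	Pafah1b3	fat_metabolism	up	0.0062	-	NA	0.27	6	135	11	25961	6.42
Q568Z9	Phyhip	fat_metabolism	up	0.0105	-	NA	0.54	4	160	17	38101	6.53
P15999	Atp5a1	energy_metabolism	down	0.0285	up	0.0001	3.49	5	295	38	59831	9.22
P31399	Atp5h	energy_metabolism	down	0.0039	-	NA	2.70	6	148	13	18809	6.17
Q561S0	Ndufa10	energy_metabolism	down	0.0190	-	NA	3.09	4	261	21	40753	7.64
Q641Y2	Ndufs2	energy_metabolism	down	0.0163	-	NA	2.46	6	247	31	52927	6.52
D3ZG43	Ndufs3	energy_metabolism	down	0.0039	-	NA	3.29	6	280	21	20190	6.32
P19234	Ndufv2	energy_metabolism	down	0.0472	-	NA	2.48	5	138	13	27703	6.23
P60901	Psma6	degradation	up	0.0039	-	NA	0.48	6	173	16	27838	6.34
P40112	Psmb3	degradation	up	0.0176	-	NA	0.27	5	124	12	23234	6.15
D4A640	Psmb4	degradation	up	0.0065	-	NA	0.56	6	102	7	25858	5.97
Q9JHW0	Psmb7	degradation	up	0.0039	-	NA	0.44	6	120	10	30250	8.13
Q4V8E2	Psmd14	degradation	up	0.0881	-	NA	0.56	4	64	7	34726	6.06
O08557	Ddah1	antioxidants	up	0.0176	-	NA	0.44	5	283	26	31805	5.75
Q9Z1B2	Gstm5	antioxidants	down	0.0065	-	NA	2.92	6	232	22	27067	6.33
Q9Z339	Gsto1	antioxidants	down	0.0547	-	NA	2.27	6	81	10	27936	6.25
Q9Z0V6	Prdx3	antioxidants	down	0.0104	-	NA	1.87	6	72	8	28563	7.14
O35244	Prdx6	antioxidants	down	0.0039	-	NA	3.75	6	207	18	24860	5.64
Q6P7P5	Bzw1	biosynthesis	up	0.0550	-	NA	0.52	4	77	10	48184	5.75
Q4KM73	Cmpk1	biosynthesis	up	0.0163	-	NA	0.55	6	149	10	22383	5.66
P62630	Eef1a1	biosynthesis	up	0.5839	-	NA	0.44	5	73	10	50424	9.1
Q68FR6	Eef1g	biosynthesis	up	0.0550	-	NA	0.37	6	235	27	50371	6.31
Q5RKI1	Eif4a2	biosynthesis	-	NA	down	0.0090	5.16	5	196	28	46601	5.33
Q32PX7	Fubp1	biosynthesis	down	0.0283	-	NA	1.78	5	97	10	67326	7.18
Q794E4	Hnrnpf	biosynthesis	up	0.0105	-	NA	0.11	4	158	21	46043	5.31
Q6AY09	Hnrnph2	biosynthesis	-	NA	up	0.0285	0.42	5	194	28	49547	5.89
P85973	Pnp	biosynthesis	up	0.0550	-	NA	0.59	6	263	31	32566	6.46
P62716	Ppp2cb	biosynthesis	-	NA	down	0.0143	2.41	4	169	16	36123	5.21
P53042	Ppp5c	biosynthesis	down	0.0758	-	NA	2.37	5	159	18	57507	5.84
F1LPS8	Pura	biosynthesis	down	0.1093	down	0.0176	1.70	6	73	12	34976	6.07
Q925G0	Rbm3	biosynthesis	down	0.0163	-	NA	1.87	5	73	5	16845	6.92
Q5XIG8	Strap	biosynthesis	up	0.0163	up	0.0163	0.38	6	141	15	38717	4.99
Q4KM49	Yars	biosynthesis	up	0.0285	up	0.0547	0.57	5	141	18	59420	6.57
P62961	Ybx1	biosynthesis	up	0.0446	-	NA	0.52	5	219	16	35709	9.87
P97697	Impa1	signal_transduction	up	0.3367	-	NA	0.48	6	214	16	30834	5.17
P62260	Ywhae	signal_transduction	up	0.3367	-	NA	0.51	6	213	34	29326	4.63
Q64640	Adk	regulation	down	0.0039	-	NA	4.50	6	129	13	40450	5.72
Q02589	Adprh	regulation	up	0.0176	-	NA	0.31	5	111	12	40220	5.62
Q07936	Anxa2	regulation	up	0.0782	-	NA	0.53	6	71	12	38939	7.55
P27139	Ca2	regulation	down	0.0104	-	NA	5.01	6	89	11	29267	6.89
P45592	Cfl1	regulation	up	0.1745	-	NA	0.56	5	154	16	18749	8.22
P08082	Cltb	regulation	down	0.0209	down	0.0209	2.31	4	104	8	25216	4.56
B0BNE5	Esd	regulation	down	0.1003	-	NA	1.86	5	181	15	31971	6.44
P07936	Gap43	regulation	up	0.0039	-	NA	0.11	6	95	7	23703	4.61
P50399	Gdi2	regulation	up	0.1093	-	NA	0.52	6	311	38	51018	5.93
Q63228	Gmfb	regulation	up	0.0039	-	NA	0.13	6	78	6	16897	5.32
P62749	Hpcal1	regulation	down	0.0374	-	NA	1.96	6	202	17	22438	5.32
O88767	Park7	regulation	down	0.1093	-	NA	1.74	6	280	21	20190	6.32
Q1RP74	Tbcb	regulation	up	0.0176	-	NA	0.32	5	196	17	27515	4.93
P70566	Tmod2	regulation	down	0.0250	-	NA	3.39	6	185	15	39468	5.34
P63029	Tpt1	regulation	up	0.0106	-	NA	0.29	5	135	10	19564	4.76
P11232	Txn	regulation	up	0.0039	-	NA	0.24	6	67	4	12008	4.8
Q920J4	Txnl1	regulation	up	0.0105	-	NA	0.19	4	257	19	32628	4.84
Q6P502	Cct3	chaperones	-	NA	up	0.0062	0.33	5	210	31	61179	6.23
Q68FQ0	Cct5	chaperones	up	0.0176	up	0.0330	0.31	5	329	43	59955	5.51
P34058	Hsp90ab1	chaperones	down	0.2733	down	0.0104	2.39	6	260	42	83571	4.97
P06761	Hspa5	chaperones	down	0.8728	down	0.0105	3.49	6	315	34	72474	5.07
P11598	Pdia3	chaperones	down	1.0000	down	0.9168	1.79	5	73	8	57044	5.88
B2RYJ7	Actr1b	structural	down	0.0782	-	NA	1.77	6	173	18	42369	5.98
Q4V7C7	Actr3	structural	up	0.0163	-	NA	0.52	6	230	27	47783	5.61
B2GUZ5	Capza1	structural	up	0.0250	-	NA	0.57	6	230	19	33060	5.43
Q5XI32	Capzb	structural	up	0.0163	-	NA	0.57	6	184	20	30952	5.69
P47819	Gfap	structural	down	0.0039	-	NA	5.72	6	381	48	49984	5.35
D4A6B2	Immt	structural	down	0.0547	-	NA	2.58	6	375	46	83104	5.34
P23565	Ina	structural	down	0.0547	-	NA	1.92	6	391	45	56253	5.2
P30009	Marcks	structural	up	0.0065	-	NA	0.40	6	109	9	29834	4.32
P19527	Nefl	structural	down	0.0039	-	NA	3.49	6	412	53	61355	4.63
P12839	Nefm	structural	down	0.0090	-	NA	2.84	5	291	48	95848	4.77
B3GNI6	Sept11	structural	down	0.0163	down	0.25059	1.87	5	69	11	50005	6.24
P13668	Stmn1	structural	up	0.3367	-	NA	0.04	6	171	14	17278	5.76
Q6AYZ1	Tuba1c	structural	down	0.0190	-	NA	3.73	4	87	8	50590	4.96
Q3KRE8	Tubb2b	structural	up	0.3472	-	NA	0.48	5	317	42	50377	4.78
Q5M7T6	Atp6v0d1	transport	up	0.0039	-	NA	0.23	5	111	11	40731	4.89
Q811Q2	Clic6	transport	down	0.0039	down	0.01902	2.43	6	204	19	64990	4.29
Q6AYH5	Dctn2	transport	up	0.0833	-	NA	0.49	4	218	21	44235	5.14
Q62871	Dync1i2	transport	down	0.1003	down	0.06789	2.13	5	111	11	71533	5.11
P55051	Fabp7	transport	up	0.0039	-	NA	0.21	6	152	12	15140	5.46
Q9Z2L0	Vdac1	transport	down	0.0500	down	0.52243	2.44	4	215	17	30851	8.62
P81155	Vdac2	transport	down	0.0039	-	NA	2.25	6	168	15	32353	7.44
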