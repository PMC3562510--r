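no	virus	chr	from	to	ori	size_bp	pbs	gag	pol	env	occurrence	reference
1	MuERV-49	1	133539144	133548197	+	9054	Q	-	+	+	U/U	I,II,III,IV
2	MuERV-31	1	166153938	166159683	+	5746	Q	+	-	-	U/T	I,II,IV
3	MuERV-30	1	184187251	184196231	+	8981	Q	+	P	+	U/T	I,II,IV
4	MuERV-33	1	193757492	193766472	+	8981	Q	+	P	-	U/T	I,II,IV
5	MuERV-35	2	57066823	57075803	-	8981	Q	+	+	+	U/T	I,II,IV
6	MuERV-3	2	156182292	156189341	-	7050	Q	+	-	+	U/U	III,IV
7	MuERV-48	3	66900000	66907716	+	7717	Q	+	-	-	U/U	I,II,III,IV
8	MuERV-55	3	151986104	151995146	+	9043	Q	+	+	+	U/U	I,II,III,IV
9	MuERV-29	4	101535762	101544743	-	8982	Q	+	P	+	U/T	I,II,IV
10	MuERV-28	4	107818639	107827621	-	8983	Q	+	+	+	U/T	I,II,IV
11	MuERV-2	4	132651872	132657538	+	5667	Q	-	-	-	U/U	I,II,III,IV
12	MuERV-6	4	133715306	133720617	+	5312	Q	+	-	-	U/U	I,II,III,IV
13	MuLV_ERV_4-5_	4	145686198	145694956	-	8759	Q	+	+	+	U/U	this study
14	XMV9	4	146592937	146601658	+	8722	Q	+	+	+	U/U	V
15	L-3-9.5	5	23206397	23215063	-	8667	P	+	+	+	U/U	I,II
16	MuLV_ERV_5-2_	5	23721126	23727971	-	6846	Q	+	-	+	U/U	this study
17	MuERV-27	5	33864636	33873616	+	8981	Q	-	+	+	U/T	I,II,IV
18	MuERV-18	5	44525599	44534580	+	8982	Q	-	+	+	U/T	I,II,IV
19	MuERV-19	5	77359541	77368522	+	8982	Q	+	+	+	U/T	I,II,IV
20	MuERV-26	7	7022622	7031603	-	8982	Q	P	-	-	U/T	I,II,IV
21	MuERV-24	7	30400226	30408924	+	8699	Q	+	+	P	U/T	I,II,IV
22	MuERV-25	7	31473659	31482639	+	8981	Q	+	P	-	U/T	I,II,IV
23	MuERV-34	7	123575623	123581296	+	5674	Q	+	-	-	U/T	I,II,IV
24	MuERV-10	8	44397084	44405817	-	8734	Q	+	+	+	U/T	I,II,IV
25	MuERV-11	8	87649754	87656141	-	6388	Q	+	P	-	U/T	I,II,IV
26	MuERV-1	8	93410190	93415857	+	5668	Q	-	-	-	U/U	I,II,III,IV
27	MuERV-12	8	122413465	122420940	-	7476	Q	-	-	+	U/T	I,II,IV
28	MuERV-8	9	41713568	41720351	-	6784	Q	-	+	+	U/U	I,II,IV
29	iLN(III)-1a	9	62286981	62295739	+	8759	Q	+	+	+	U/U	I
30	K-4-11.10a	10	8263933	8271066	-	7134	Q	-	-	-	U/T	I,II
31	MuERV-53	10	22454084	22463128	+	9045	Q	+	+	+	U/U	I,II,III,IV
32	MuERV-17	10	41156454	41165434	+	8981	Q	+	+	+	U/T	I,II,IV
33	BM-a-2.11e	11	5905655	5911518	+	5864	Q	-	-	-	B/B	III
34	MuERV-22	11	6649425	6658394	-	8970	Q	+	-	+	U/T	I,II,IV
35	MuERV-23	11	820301	8829280	+	8980	Q	+	+	+	U/T	I,II,IV
36	MuERV-50	11	60392151	60399510	-	7360	Q	-	P	-	U/U	I,II,III,IV
37	MuERV-51	11	76362310	76371354	+	9045	Q	+	+	+	U/U	I,II,III,IV
38	MuERV-38	11	88751494	88758280	-	6787	Q	+	-	+	U/T	I,II,IV
39	MuERV-37	12	20704753	20710513	+	5761	Q	-	-	-	U/T	I,II,IV
40	MuERV-16	12	55875211	55884192	+	8982	Q	+	+	+	U/T	IV
41	MuERV-5	13	67985825	67994511	-	8687	Q	+	+	+	U/U	I,II,III,IV
42	MuERV-21	13	99756230	99765210	-	8981	Q	+	P	+	U/T	I,II,IV
43	MuERV-7	14	54912048	54917591	-	5544	Q	+	-	-	U/U	IV
44	L-1-2.14	14	55149203	55157025	-	7823	Q	P	+	+	U/U	I,II
45	MuERV-15	15	76390247	76397432	-	7186	Q	-	-	+	U/T	I,II,IV
46	U-1-5.16	16	76135288	76144269	-	8982	Q	-	P	-	U/T	I,II
47	MuERV-14	16	93697702	93706682	-	8981	Q	-	+	+	U/T	I,IV
48	MuERV-20	18	82862943	82871822	+	8880	Q	-	+	+	U/T	I,II,IV
49	MuERV-32	19	38449512	38456573	+	7062	Q	-	P	-	U/T	I,II,IV
50	MuERV-9	19	61001210	61009936	-	8727	Q	+	+	+	U/U	I,II,IV
51	MuERV-13	X	15051174	15060154	+	8981	Q	+	P	+	U/T	I,II,IV
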