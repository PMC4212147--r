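index	smarts	name
1	[OX2H]	hydroxyl
2	[OX2H][CX4]	aliphatic alcohol
3	[OX2H][CX4H2]	primary alcohol
4	[OX2H][CX4H1]	secondary alcohol
5	[OX2H][CX4H0]	tertiary alcohol
6	[OX2H]c	phenol
7	[OX2H][CX3]=[CX3]	enol
8	[OX2]([#6])[#6]	ether
9	[OX2]([CX4])[CX4]	dialkyl ether
10	[OX2](c)[CX4]	aryl alkyl ether
11	[OX2](c)c	diaryl ether
12	[OX2R]	ring ether
13	[OX2r3]	epoxide
14	[CX4]([OX2])[OX2]	acetal/ketal carbon
15	[OX2][OX2]	peroxide
16	[OX1-]	oxide anion
17	[CX3]=[OX1]	carbonyl
18	[CX3H1]=[OX1]	aldehyde
19	[#6][CX3](=[OX1])[#6]	ketone
20	c[CX3](=[OX1])[#6]	aryl ketone
21	[CX3](=[OX1])[OX2H]	carboxylic acid
22	[CX3](=[OX1])[OX1-]	carboxylate anion
23	[CX3](=[OX1])[OX2][#6]	ester
24	[CX3](=[OX1])[OX2][CX4]	alkyl ester
25	[CX3](=[OX1])[OX2]c	aryl ester
26	[CX3R](=[OX1])[OX2R]	lactone (ring ester)
27	[OX2][CX3](=[OX1])[OX2]	carbonate
28	[CX3](=[OX1])[OX2][CX3]=[OX1]	anhydride
29	[CX3](=[OX1])Cl	acyl chloride
30	[CX3](=[OX1])[NX3]	amide
31	[CX3](=[OX1])[NX3H2]	primary amide
32	[CX3](=[OX1])[NX3H1]	secondary amide
33	[CX3](=[OX1])[NX3H0]	tertiary amide
34	[CX3R](=[OX1])[NX3R]	lactam (ring amide)
35	[NX3][CX3](=[OX1])[NX3]	urea motif
36	[NX3][CX3](=[OX1])[OX2]	carbamate
37	[CX3]=[CX3][CX3]=[OX1]	alpha,beta-unsat. carbonyl
38	[CX3](=[OX1])[CX4][CX3]=[OX1]	1,3-dicarbonyl
39	[NX3H2]	primary amine
40	[NX3H2][CX4]	primary aliphatic amine
41	[NX3H2]c	aniline nitrogen
42	[NX3H1]([#6])[#6]	secondary amine
43	[NX3H1]([CX4])[CX4]	secondary aliphatic amine
44	[NX3H0]([#6])([#6])[#6]	tertiary amine
45	[NX3H0]([CX4])([CX4])[CX4]	tertiary aliphatic amine
46	[NX3H1R]	ring secondary amine
47	[NX3H0R]	ring tertiary amine
48	[NX4+]	ammonium (quaternary)
49	n	aromatic nitrogen
50	[nH]	aromatic NH
51	[nX2H0]	pyridine-type nitrogen
52	[NX2]=[CX3]	imine
53	[NX2](=[CX3])[OX2H]	oxime
54	[NX2](=[CX3])[NX3]	hydrazone
55	[CX2]#[NX1]	nitrile
56	c[CX2]#[NX1]	aromatic nitrile
57	[NX3+](=[OX1])[OX1-]	nitro group
58	c[NX3+](=[OX1])[OX1-]	aromatic nitro
59	[NX2]=[NX2]	azo
60	[NX2]=[NX2+]=[NX1-]	azide
61	[NX3][NX3]	hydrazine motif
62	[NX3][OX2H]	hydroxylamine motif
63	[NX2]=[CX2]=[OX1]	isocyanate
64	[NX2]=[CX2]=[SX1]	isothiocyanate
65	[NX3][CX3]=[NX2]	amidine
66	[NX3][CX3](=[NX2])[NX3]	guanidine
67	[SX2H]	thiol
68	[SX2]([#6])[#6]	sulfide
69	[SX2]([CX4])[CX4]	dialkyl sulfide
70	[SX2][SX2]	disulfide
71	s	aromatic sulfur
72	[SX3]=[OX1]	sulfoxide
73	[SX4](=[OX1])=[OX1]	sulfone
74	[SX4](=[OX1])(=[OX1])[OX2H]	sulfonic acid
75	[SX4](=[OX1])(=[OX1])[NX3]	sulfonamide
76	[SX4](=[OX1])(=[OX1])[OX2][#6]	sulfonate ester
77	[CX3]=[SX1]	thiocarbonyl
78	[SX2][CX3]=[OX1]	thioester
79	[SX2R]	ring sulfur
80	[#15]	phosphorus any
81	[PX4]=[OX1]	phosphoryl
82	[PX4](=[OX1])([OX2])[OX2]	phosphate ester
83	[PX4](=[OX1])[#6]	phosphonate carbon
84	[PX3]	trivalent phosphorus
85	[#5]	boron any
86	[BX3]([OX2])[OX2]	boronic acid/ester
87	F[#6]	fluorine on carbon
88	F[CX4]	fluorine aliphatic
89	Fc	fluorine aromatic
90	[CX4](F)(F)F	trifluoromethyl
91	Cl[#6]	chlorine on carbon
92	Cl[CX4]	chlorine aliphatic
93	Clc	chlorine aromatic
94	[CX4](Cl)Cl	gem-dichloro
95	Br[#6]	bromine on carbon
96	Br[CX4]	bromine aliphatic
97	Brc	bromine aromatic
98	I[#6]	iodine on carbon
99	I[CX4]	iodine aliphatic
100	Ic	iodine aromatic
101	[F,Cl,Br,I][CX3]	halogen on sp2 carbon
102	[F,Cl,Br,I][CX4][CX4][F,Cl,Br,I]	vicinal dihalide
103	[CX4H3]	methyl
104	[CX4H2]	methylene
105	[CX4H1]	methine
106	[CX4H0]	quaternary carbon
107	[CX4H3]c	methyl on aromatic
108	[CX4H3][CX4H2]	ethyl group
109	[CX4H1]([CX4H3])[CX4H3]	isopropyl
110	[CX4H0]([CX4H3])([CX4H3])[CX4H3]	tert-butyl
111	[CX4H2][CX4H2][CX4H2][CX4H2]	long chain (C4)
112	[CX3]=[CX3]	alkene
113	[CX3H2]=[CX3]	terminal alkene
114	[CX3]=[CX3][CX3]=[CX3]	conjugated diene
115	c[CX3]=[CX3]	vinyl on aromatic
116	[CX2]#[CX2]	alkyne
117	[CX2H1]#[CX2]	terminal alkyne
118	[CX4][CX3]=[CX3]	allylic carbon
119	[CX4]c	benzylic carbon
120	a	aromatic atom
121	c	aromatic carbon
122	c1ccccc1	benzene ring
123	a1aaaa1	aromatic 5-ring
124	a1aaaaa1	aromatic 6-ring
125	[cR2]	fused aromatic atom
126	c-c	biaryl bond
127	[R]	ring atom
128	[R2]	atom in two rings
129	[CX4R]	aliphatic ring carbon
130	[r3]	3-membered ring atom
131	[r4]	4-membered ring atom
132	[r5]	5-membered ring atom
133	[r6]	6-membered ring atom
134	[r7]	7-membered ring atom
135	[a;!#6]	heteroaromatic atom
136	[!#6;!#1;R]	aliphatic heteroring atom
137	c[OX2H]	aromatic hydroxyl
138	c[OX2][CX4]	aromatic ether oxygen
139	c[NX3]	aromatic amine
140	c[F,Cl,Br,I]	aromatic halide
141	c[CX3](=[OX1])[OX2H]	aromatic carboxyl
142	c[CX3]=[OX1]	aromatic carbonyl
143	c[SX2]	aromatic sulfur subst
144	[NX3][CX4][CX3](=[OX1])[OX2H]	alpha-amino acid motif
145	[OX2H][CX4][CX3]=[OX1]	beta-hydroxy carbonyl
146	[OX2H][CX4][CX4][OX2H]	vicinal diol
147	[NX3][CX4][CX4][OX2H]	amino alcohol
148	[OX2H][CX4][CX4][F,Cl,Br,I]	halohydrin
149	c[CX3](=[OX1])[NX3]	aryl amide
150	[CX3](=[OX1])[NX3]c	anilide
151	[OX2H]c1ccccc1[CX3]=[OX1]	salicyl motif
152	[OX2H]c1ccccc1[OX2H]	catechol motif
153	c1ccccc1[CX3]=[OX1]	benzoyl
154	c[CX4][CX4]	phenethyl motif
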