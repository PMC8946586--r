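node_index	region_label	rsn_label
1	PreCG.L	sensorimotor
2	PreCG.R	sensorimotor
3	SFGdor.L	default_mode
4	SFGdor.R	default_mode
5	ORBsup.L	default_mode
6	ORBsup.R	default_mode
7	MFG.L	attention
8	MFG.R	attention
9	ORBmid.L	default_mode
10	ORBmid.R	default_mode
11	IFGoperc.L	attention
12	IFGoperc.R	attention
13	IFGtriang.L	attention
14	IFGtriang.R	attention
15	ORBinf.L	default_mode
16	ORBinf.R	default_mode
17	ROL.L	sensorimotor
18	ROL.R	sensorimotor
19	SMA.L	sensorimotor
20	SMA.R	sensorimotor
21	OLF.L	default_mode
22	OLF.R	default_mode
23	SFGmed.L	default_mode
24	SFGmed.R	default_mode
25	ORBsupmed.L	default_mode
26	ORBsupmed.R	default_mode
27	REC.L	default_mode
28	REC.R	default_mode
29	INS.L	attention
30	INS.R	attention
31	ACG.L	default_mode
32	ACG.R	default_mode
33	DCG.L	default_mode
34	DCG.R	default_mode
35	PCG.L	default_mode
36	PCG.R	default_mode
37	HIP.L	subcortical
38	HIP.R	subcortical
39	PHG.L	subcortical
40	PHG.R	subcortical
41	AMYG.L	subcortical
42	AMYG.R	subcortical
43	CAL.L	visual
44	CAL.R	visual
45	CUN.L	visual
46	CUN.R	visual
47	LING.L	visual
48	LING.R	visual
49	SOG.L	visual
50	SOG.R	visual
51	MOG.L	visual
52	MOG.R	visual
53	IOG.L	visual
54	IOG.R	visual
55	FFG.L	visual
56	FFG.R	visual
57	PoCG.L	sensorimotor
58	PoCG.R	sensorimotor
59	SPG.L	attention
60	SPG.R	attention
61	IPL.L	attention
62	IPL.R	attention
63	SMG.L	attention
64	SMG.R	attention
65	ANG.L	default_mode
66	ANG.R	default_mode
67	PCUN.L	default_mode
68	PCUN.R	default_mode
69	PCL.L	sensorimotor
70	PCL.R	sensorimotor
71	CAU.L	subcortical
72	CAU.R	subcortical
73	PUT.L	subcortical
74	PUT.R	subcortical
75	PAL.L	subcortical
76	PAL.R	subcortical
77	THA.L	subcortical
78	THA.R	subcortical
79	HES.L	sensorimotor
80	HES.R	sensorimotor
81	STG.L	sensorimotor
82	STG.R	sensorimotor
83	TPOsup.L	default_mode
84	TPOsup.R	default_mode
85	MTG.L	default_mode
86	MTG.R	default_mode
87	TPOmid.L	default_mode
88	TPOmid.R	default_mode
89	ITG.L	default_mode
90	ITG.R	default_mode
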