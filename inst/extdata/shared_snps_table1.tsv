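index	variant_id	chrom	source
1	rs112588918	19	printed
2	rs2199575	19	printed
3	rs57537848	19	printed
4	rs11666329	19	printed
5	rs2972559	19	printed
6	rs71338733	19	printed
7	rs73050205	19	printed
8	rs199956232	19	printed
9	rs4803763	19	printed
10	rs4803764	19	printed
11	rs142042446	19	printed
12	rs12972156	19	printed
13	rs12972970	19	printed
14	rs34342646	19	printed
15	rs283811	19	printed
16	rs283815	19	printed
17	rs6857	19	printed
18	rs71352238	19	printed
19	rs184017	19	printed
20	rs2075650	19	printed
21	rs157581	19	printed
22	rs34095326	19	printed
23	rs34404554	19	printed
24	rs11556505	19	printed
25	rs157582	19	printed
26	rs59007384	19	printed
27	rs769449	19	printed
28	rs429358	19	printed
29	rs75627662	19	printed
30	rs10414043	19	printed
31	rs7256200	19	printed
32	rs483082	19	printed
33	rs438811	19	printed
34	rs34954997	19	printed
35	rs5117	19	printed
36	rs12721046	19	printed
37	rs12721051	19	printed
38	rs56131196	19	printed
39	rs4420638	19	printed
40	rs814573	19	printed
41	rs157592	19	printed
42	rs111789331	19	printed
43	rs66626994	19	printed
44	rs576224725	6	printed
45	rs3095250	6	printed
46	rs3132496	6	printed
47	rs3095248	6	printed
48	rs3130712	6	printed
49	rs3130406	6	printed
50	rs3130535	6	printed
51	rs3130688	6	printed
52	rs3134766	6	printed
53	rs3130536	6	printed
54	rs3134764	6	printed
55	rs3134763	6	printed
56	rs2394900	6	printed
57	rs34763471	6	printed
58	rs2394901	6	printed
59	rs3095244	6	printed
60	rs3134757	6	printed
61	rs112077259	6	printed
62	rs2894188	6	printed
63	rs3095242	6	printed
64	rs3095241	6	printed
65	rs3130413	6	printed
66	rs2394906	6	printed
67	rs3130416	6	printed
68	rs3130418	6	printed
69	rs3134750	6	printed
70	rs3130431	6	printed
71	rs9264187	6	printed
72	rs7769393	6	printed
73	rs4458721	6	printed
74	rs35899943	6	printed
75	rs1980496	6	printed
76	rs9268433	6	printed
77	rs3793127	6	printed
78	rs3763309	6	printed
79	rs3763312	6	printed
80	rs9269041	6	printed
81	rs35743245	6	printed
82	rs36096565	6	printed
83	rs35972518	6	printed
84	rs35917796	6	printed
85	rs35380574	6	printed
86	rs35395738	6	printed
87	rs35472547	6	printed
88	rs34939562	6	printed
89	rs34924558	6	printed
90	rs34496598	6	printed
91	rs35525122	6	printed
92	rs34350244	6	printed
93	rs34535888	6	printed
94	rs34553045	6	printed
95	rs2760980	6	printed
96	rs2760983	6	printed
97	rs113134061	6	printed
98	rs2760984	6	printed
99	rs2454139	6	printed
100	rs34117221	6	printed
101	rs34331363	6	printed
102	rs35226637	6	printed
103	rs35653258	6	printed
104	rs2647059	6	printed
105	rs2647062	6	printed
106	rs558721	6	printed
107	rs679242	6	printed
108	rs2760990	6	printed
109	rs2647066	6	printed
110	rs17425622	6	printed
111	rs601148	6	printed
112	rs601945	6	printed
113	rs3130411	6	printed
114	rs9271494	6	printed
115	rs6917729	6	printed
116	rs6605556	6	printed
117	rs9268455	6	printed
118	syn-chr6-001	6	synthetic_padding
119	syn-chr6-002	6	synthetic_padding
120	syn-chr6-003	6	synthetic_padding
121	syn-chr6-004	6	synthetic_padding
122	syn-chr6-005	6	synthetic_padding
123	syn-chr6-006	6	synthetic_padding
124	syn-chr6-007	6	synthetic_padding
125	syn-chr6-008	6	synthetic_padding
126	syn-chr6-009	6	synthetic_padding
127	syn-chr6-010	6	synthetic_padding
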