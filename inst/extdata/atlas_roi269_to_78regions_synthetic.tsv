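roi	region	hemisphere	excluded
1	PreCG	L	0
2	PreCG	L	0
3	PreCG	L	0
4	PreCG	L	0
5	PreCG	R	0
6	PreCG	R	0
7	PreCG	R	0
8	PreCG	R	0
9	SFGdor	L	0
10	SFGdor	L	0
11	SFGdor	L	0
12	SFGdor	L	0
13	SFGdor	R	0
14	SFGdor	R	0
15	SFGdor	R	0
16	SFGdor	R	0
17	ORBsup	L	0
18	ORBsup	L	0
19	ORBsup	L	0
20	ORBsup	L	0
21	ORBsup	R	0
22	ORBsup	R	0
23	ORBsup	R	0
24	ORBsup	R	0
25	MFG	L	0
26	MFG	L	0
27	MFG	L	0
28	MFG	L	0
29	MFG	R	0
30	MFG	R	0
31	MFG	R	0
32	MFG	R	0
33	ORBmid	L	0
34	ORBmid	L	0
35	ORBmid	L	0
36	ORBmid	L	0
37	ORBmid	R	0
38	ORBmid	R	0
39	ORBmid	R	0
40	ORBmid	R	0
41	IFGoperc	L	0
42	IFGoperc	L	0
43	IFGoperc	L	0
44	IFGoperc	L	0
45	IFGoperc	R	0
46	IFGoperc	R	0
47	IFGoperc	R	0
48	IFGoperc	R	0
49	IFGtriang	L	0
50	IFGtriang	L	0
51	IFGtriang	L	0
52	IFGtriang	L	0
53	IFGtriang	R	0
54	IFGtriang	R	0
55	IFGtriang	R	0
56	IFGtriang	R	0
57	ORBinf	L	0
58	ORBinf	L	0
59	ORBinf	L	0
60	ORBinf	L	0
61	ORBinf	R	0
62	ORBinf	R	0
63	ORBinf	R	0
64	ORBinf	R	0
65	ROL	L	0
66	ROL	L	0
67	ROL	L	0
68	ROL	L	0
69	ROL	R	0
70	ROL	R	0
71	ROL	R	0
72	ROL	R	0
73	SMA	L	0
74	SMA	L	0
75	SMA	L	0
76	SMA	L	0
77	SMA	R	0
78	SMA	R	0
79	SMA	R	0
80	SMA	R	0
81	OLF	L	0
82	OLF	L	0
83	OLF	L	0
84	OLF	L	0
85	OLF	R	0
86	OLF	R	0
87	OLF	R	0
88	OLF	R	0
89	SFGmed	L	0
90	SFGmed	L	0
91	SFGmed	L	0
92	SFGmed	L	0
93	SFGmed	R	0
94	SFGmed	R	0
95	SFGmed	R	0
96	SFGmed	R	0
97	ORBsupmed	L	0
98	ORBsupmed	L	0
99	ORBsupmed	L	0
100	ORBsupmed	L	0
101	ORBsupmed	R	0
102	ORBsupmed	R	0
103	ORBsupmed	R	0
104	ORBsupmed	R	0
105	REC	L	0
106	REC	L	0
107	REC	L	0
108	REC	L	0
109	REC	R	0
110	REC	R	0
111	REC	R	0
112	REC	R	0
113	INS	L	0
114	INS	L	0
115	INS	L	0
116	INS	L	0
117	INS	R	0
118	INS	R	0
119	INS	R	0
120	INS	R	0
121	ACG	L	0
122	ACG	L	0
123	ACG	L	0
124	ACG	L	0
125	ACG	R	0
126	ACG	R	0
127	ACG	R	0
128	ACG	R	0
129	DCG	L	0
130	DCG	L	0
131	DCG	L	0
132	DCG	L	0
133	DCG	R	0
134	DCG	R	0
135	DCG	R	0
136	DCG	R	0
137	PCG	L	0
138	PCG	L	0
139	PCG	L	0
140	PCG	R	0
141	PCG	R	0
142	PCG	R	0
143	HIP	L	0
144	HIP	L	0
145	HIP	L	0
146	HIP	R	0
147	HIP	R	0
148	HIP	R	0
149	PHG	L	0
150	PHG	L	0
151	PHG	L	0
152	PHG	R	0
153	PHG	R	0
154	PHG	R	0
155	AMYG	L	0
156	AMYG	L	0
157	AMYG	L	0
158	AMYG	R	0
159	AMYG	R	0
160	AMYG	R	0
161	CAL	L	0
162	CAL	L	0
163	CAL	L	0
164	CAL	R	0
165	CAL	R	0
166	CAL	R	0
167	CUN	L	0
168	CUN	L	0
169	CUN	L	0
170	CUN	R	0
171	CUN	R	0
172	CUN	R	0
173	LING	L	0
174	LING	L	0
175	LING	L	0
176	LING	R	0
177	LING	R	0
178	LING	R	0
179	SOG	L	0
180	SOG	L	0
181	SOG	L	0
182	SOG	R	0
183	SOG	R	0
184	SOG	R	0
185	MOG	L	0
186	MOG	L	0
187	MOG	L	0
188	MOG	R	0
189	MOG	R	0
190	MOG	R	0
191	IOG	L	0
192	IOG	L	0
193	IOG	L	0
194	IOG	R	0
195	IOG	R	0
196	IOG	R	0
197	FFG	L	0
198	FFG	L	0
199	FFG	L	0
200	FFG	R	0
201	FFG	R	0
202	FFG	R	0
203	PoCG	L	0
204	PoCG	L	0
205	PoCG	L	0
206	PoCG	R	0
207	PoCG	R	0
208	PoCG	R	0
209	SPG	L	0
210	SPG	L	0
211	SPG	L	0
212	SPG	R	0
213	SPG	R	0
214	SPG	R	0
215	IPL	L	0
216	IPL	L	0
217	IPL	L	0
218	IPL	R	0
219	IPL	R	0
220	IPL	R	0
221	SMG	L	0
222	SMG	L	0
223	SMG	L	0
224	SMG	R	0
225	SMG	R	0
226	SMG	R	0
227	ANG	L	0
228	ANG	L	0
229	ANG	L	0
230	ANG	R	0
231	ANG	R	0
232	ANG	R	0
233	PCUN	L	0
234	PCUN	L	0
235	PCUN	L	0
236	PCUN	R	0
237	PCUN	R	0
238	PCUN	R	0
239	PCL	L	0
240	PCL	L	0
241	PCL	L	0
242	PCL	R	0
243	PCL	R	0
244	PCL	R	0
245	CAU	L	0
246	CAU	L	0
247	CAU	L	0
248	CAU	R	0
249	CAU	R	0
250	CAU	R	0
251	PUT	L	0
252			1
253	PUT	L	0
254	PUT	L	0
255	PUT	R	0
256	PUT	R	0
257	PUT	R	0
258	PAL	L	0
259	PAL	L	0
260	PAL	L	0
261	PAL	R	0
262	PAL	R	0
263	PAL	R	0
264	THA	L	0
265	THA	L	0
266	THA	L	0
267	THA	R	0
268	THA	R	0
269	THA	R	0
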