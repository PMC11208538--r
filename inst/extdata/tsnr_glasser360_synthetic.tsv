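roi_id	tsnr
1	0.248214
2	0.527273
3	0.346324
4	0.279762
5	0.408333
6	0.341176
7	0.323529
8	1
9	0.327941
10	0.498148
11	0.203571
12	0.536364
13	0.297619
14	0.356452
15	0.314706
16	0.190625
17	0.487037
18	0.590625
19	0.461111
20	0.313971
21	0.1125
22	0.394355
23	0.434167
24	0.516667
25	0.488889
26	0.596875
27	0.350806
28	0.490741
29	0.55625
30	0.333824
31	0.477778
32	0.531818
33	0.8
34	0.56875
35	0.382258
36	0.09
37	0.406667
38	0.396774
39	0.4225
40	0.317647
41	0.436667
42	0.329412
43	0.08
44	0.433333
45	0.373387
46	0.335294
47	0.232143
48	0.565625
49	0.219643
50	0.309559
51	0.84
52	0.59375
53	0.349265
54	0.282143
55	0.439167
56	0.223214
57	0.4025
58	0.178125
59	0.401667
60	0.425
61	0.320588
62	0.524242
63	0.289286
64	0.584375
65	0.485185
66	0.343382
67	0.259524
68	0.307353
69	0.300735
70	0.4425
71	0.369355
72	0.255952
73	0.47037
74	0.391129
75	0.423333
76	0.263095
77	0.313235
78	0.326471
79	0.316176
80	0.277381
81	0.06
82	0.3375
83	0.389516
84	0.235714
85	0.449167
86	0.494444
87	0.4275
88	0.507576
89	0.205357
90	0.377419
91	0.217857
92	0.416667
93	0.171875
94	0.315441
95	0.525758
96	0.468519
97	0.466667
98	0.42
99	0.405
100	0.395968
101	0.303676
102	0.125
103	0.428333
104	0.221429
105	0.360484
106	0.530303
107	0.375
108	0.165625
109	0.68
110	0.347059
111	0.233929
112	0.379032
113	0.270238
114	0.258333
115	0.345588
116	0.305882
117	0.445
118	0.301471
119	0.3125
120	0.264286
121	0.376613
122	0.441667
123	0.354032
124	0.325
125	0.379839
126	0.435
127	0.443333
128	0.347794
129	0.518182
130	0.372581
131	0.210714
132	0.492593
133	0.226786
134	0.411667
135	0.316912
136	0.515152
137	0.50303
138	0.284524
139	0.4175
140	0.348529
141	0.76
142	0.305147
143	0.370161
144	0.327206
145	0.216071
146	0.2375
147	0.368548
148	0.288095
149	0.374194
150	0.208929
151	0.214286
152	0.435833
153	0.47963
154	0.280952
155	0.385484
156	0.340441
157	0.265476
158	0.16875
159	0.571875
160	0.415833
161	0.266667
162	0.72
163	0.419167
164	0.319118
165	0.455556
166	0.38871
167	0.353226
168	0.41
169	0.07
170	0.351613
171	0.542424
172	0.398387
173	0.522727
174	0.387097
175	0.429167
176	0.54697
177	0.252381
178	0.414167
179	0.5875
180	0.244643
181	0.424167
182	0.339706
183	0.159375
184	0.92
185	0.43
186	0.553125
187	0.425833
188	0.302206
189	0.481481
190	0.291667
191	0.409167
192	0.383065
193	0.308824
194	0.344118
195	0.446667
196	0.472222
197	0.257143
198	0.399194
199	0.260714
200	0.430833
201	0.292857
202	0.366129
203	0.358871
204	0.338235
205	0.383871
206	0.336029
207	0.184375
208	0.355645
209	0.225
210	0.342647
211	0.27619
212	0.539394
213	0.393548
214	0.302941
215	0.331618
216	0.294048
217	0.96
218	0.4125
219	0.228571
220	0.311765
221	0.375806
222	0.29881
223	0.318382
224	0.311029
225	0.1625
226	0.438333
227	0.261905
228	0.483333
229	0.392742
230	0.462963
231	0.474074
232	0.334559
233	0.88
234	0.296429
235	0.367742
236	0.444167
237	0.1375
238	0.403333
239	0.519697
240	0.254762
241	0.371774
242	0.366935
243	0.575
244	0.510606
245	0.4475
246	0.44
247	0.4325
248	0.344853
249	0.242857
250	0.397581
251	0.540909
252	0.286905
253	0.504545
254	0.322794
255	0.548485
256	0.445833
257	0.352419
258	0.58125
259	0.390323
260	0.400833
261	0.404167
262	0.420833
263	0.513636
264	0.362903
265	0.333088
266	0.241071
267	0.196875
268	0.239286
269	0.267857
270	0.451852
271	0.405833
272	0.440833
273	0.413333
274	0.364516
275	0.230357
276	0.5625
277	0.330882
278	0.354839
279	0.378226
280	0.36371
281	0.365323
282	0.528788
283	0.15625
284	0.290476
285	0.321324
286	0.358065
287	0.421667
288	0.278571
289	0.1875
290	0.459259
291	0.509091
292	0.341912
293	0.359677
294	0.512121
295	0.448333
296	0.18125
297	0.357258
298	0.457407
299	0.410833
300	0.269048
301	0.36129
302	0.506061
303	0.319853
304	0.370968
305	0.25119
306	0.322059
307	0.325735
308	0.332353
309	0.246429
310	0.38629
311	0.533333
312	0.521212
313	0.207143
314	0.380645
315	0.285714
316	0.27381
317	0.308088
318	0.384677
319	0.559375
320	0.501515
321	0.464815
322	0.545455
323	0.426667
324	0.295238
325	0.330147
326	0.418333
327	0.534848
328	0.431667
329	0.338971
330	0.324265
331	0.4375
332	0.175
333	0.381452
334	0.304412
335	0.543939
336	0.272619
337	0.496296
338	0.362097
339	0.395161
340	0.4075
341	0.391935
342	0.275
343	0.283333
344	0.336765
345	0.253571
346	0.387903
347	0.271429
348	0.475926
349	0.578125
350	0.2125
351	0.537879
352	0.64
353	0.19375
354	0.201786
355	0.415
356	0.306618
357	0.328676
358	0.153125
359	0.310294
360	0.453704
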