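roi_id	tsnr
1	0.272059
2	0.490476
3	0.369079
4	0.306034
5	0.420139
6	0.364474
7	0.347414
8	1
9	0.352632
10	0.47619
11	0.225
12	0.495238
13	0.533333
14	0.318966
15	0.376974
16	0.337069
17	0.215909
18	0.557143
19	0.548611
20	0.471429
21	0.597619
22	0.460317
23	0.336207
24	0.155
25	0.409028
26	0.522222
27	0.538889
28	0.441667
29	0.484921
30	0.472222
31	0.692308
32	0.372368
33	0.473016
34	0.561905
35	0.357895
36	0.46746
37	0.492857
38	0.846154
39	0.57619
40	0.569048
41	0.398026
42	0.125
43	0.41875
44	0.531944
45	0.411111
46	0.431944
47	0.340517
48	0.44375
49	0.353947
50	0.0375
51	0.440972
52	0.390789
53	0.359211
54	0.258824
55	0.57381
56	0.245455
57	0.331034
58	0.876923
59	0.541667
60	0.496825
61	0.371711
62	0.307759
63	0.445833
64	0.251471
65	0.415278
66	0.206818
67	0.414583
68	0.434028
69	0.493651
70	0.343966
71	0.527778
72	0.312931
73	0.499206
74	0.592857
75	0.470635
76	0.366447
77	0.283824
78	0.328448
79	0.559524
80	0.32069
81	0.448611
82	0.3875
83	0.279412
84	0.464286
85	0.40625
86	0.432639
87	0.288235
88	0.461905
89	0.335345
90	0.351316
91	0.338793
92	0.30431
93	0.484127
94	0.0125
95	0.361184
96	0.404861
97	0.552381
98	0.261765
99	0.723077
100	0.501389
101	0.436111
102	0.511111
103	0.227273
104	0.394079
105	0.243182
106	0.427083
107	0.202273
108	0.337931
109	0.529167
110	0.486508
111	0.485714
112	0.429861
113	0.463492
114	0.417361
115	0.545833
116	0.410417
117	0.324138
118	0.16
119	0.436806
120	0.450794
121	0.247727
122	0.392105
123	0.438194
124	0.447917
125	0.753846
126	0.260294
127	0.395395
128	0.297059
129	0.368421
130	0.326724
131	0.49127
132	0.334483
133	0.469048
134	0.375
135	0.349138
136	0.396053
137	0.461111
138	0.494444
139	0.390132
140	0.498413
141	0.254412
142	0.540278
143	0.506944
144	0.309483
145	0.455556
146	0.371053
147	0.815385
148	0.325862
149	0.420833
150	0.419444
151	0.388158
152	0.413194
153	0.351974
154	0.240909
155	0.426389
156	0.263235
157	0.386842
158	0.487302
159	0.312069
160	0.391447
161	0.231818
162	0.238636
163	0.43125
164	0.492063
165	0.571429
166	0.306897
167	0.406944
168	0.401389
169	0.363816
170	0.291176
171	0.195
172	0.416667
173	0.48254
174	0.446528
175	0.292647
176	0.784615
177	0.289706
178	0.342241
179	0.479365
180	0.422917
181	0.374342
182	0.234091
183	0.025
184	0.373026
185	0.547222
186	0.474603
187	0.466667
188	0.526389
189	0.421528
190	0.19
191	0.453175
192	0.554762
193	0.275
194	0.457143
195	0.445139
196	0.595238
197	0.269118
198	0.282353
199	0.398684
200	0.363158
201	0.18
202	0.399342
203	0.938462
204	0.409722
205	0.5125
206	0.488889
207	0.413889
208	0.322414
209	0.544444
210	0.314655
211	0.443056
212	0.430556
213	0.330172
214	0.380921
215	0.367105
216	0.369737
217	0.435417
218	0.488095
219	0.280882
220	0.388816
221	0.285294
222	0.382237
223	0.404167
224	0.534722
225	0.315517
226	0.447222
227	0.402083
228	0.405556
229	0.361842
230	0.418056
231	0.359868
232	0.438889
233	0.211364
234	0.389474
235	0.252941
236	0.365789
237	0.303448
238	0.339655
239	0.428472
240	0.323276
241	0.355921
242	0.316379
243	0.385526
244	0.530556
245	0.380263
246	0.255882
247	0.333621
248	0.630769
249	0.367763
250	0.319828
251	0.341379
252	0.332759
253	0.185
254	0.365132
255	0.377632
256	0.286765
257	0.375658
258	0.427778
259	0.483333
260	0.403472
261	0.496032
262	0.318103
263	0.476984
264	0.357237
265	0.408333
266	0.480159
267	0.400694
268	0.346552
269	0.580952
270	0.442361
271	0.383553
272	0.267647
273	0.433333
274	0.969231
275	0.311207
276	0.465873
277	0.34569
278	0.277941
279	0.588095
280	0.370395
281	0.459524
282	0.384211
283	0.590476
284	0.425
285	0.4375
286	0.440278
287	0.321552
288	0.518056
289	0.407639
290	0.543056
291	0.266176
292	0.325
293	0.386184
294	0.220455
295	0.264706
296	0.294118
297	0.165
298	0.519444
299	0.454762
300	0.444444
301	0.397368
302	0.257353
303	0.425694
304	0.3625
305	0.396711
306	0.434722
307	0.508333
308	0.566667
309	0.423611
310	0.583333
311	0.175
312	0.513889
313	0.356579
314	0.376316
315	0.350658
316	0.449306
317	0.907692
318	0.305172
319	0.213636
320	0.310345
321	0.353289
322	0.481746
323	0.489683
324	0.392763
325	0.393421
326	0.475397
327	0.209091
328	0.515278
329	0.382895
330	0.354605
331	0.661538
332	0.273529
333	0.358553
334	0.270588
335	0.457937
336	0.469841
337	0.5375
338	0.344828
339	0.229545
340	0.308621
341	0.327586
342	0.564286
343	0.313793
344	0.276471
345	0.523611
346	0.300862
347	0.462698
348	0.4125
349	0.578571
350	0.355263
351	0.536111
352	0.47381
353	0.343103
354	0.585714
355	0.301724
356	0.477778
357	0.373684
358	0.451587
359	0.424306
360	0.394737
361	0.381579
362	0.516667
363	0.439583
364	0.415972
365	0.379605
366	0.411806
367	0.402778
368	0.317241
369	0.298529
370	0.295588
371	0.360526
372	0.465079
373	0.497619
374	0.218182
375	0.453968
376	0.478571
377	0.468254
378	0.509722
379	0.302586
380	0.429167
381	0.222727
382	0.384868
383	0.378289
384	0.378947
385	0.236364
386	0.204545
387	0.452381
388	0.456349
389	0.505556
390	0.17
391	0.502778
392	0.520833
393	0.348276
394	0.422222
395	0.32931
396	0.45873
397	0.504167
398	0.525
399	0.480952
400	0.331897
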