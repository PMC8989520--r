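position_1based	coverage_fraction	start_count	end_count
1	0.00000000	0	0
2	0.00000000	0	0
3	0.00000000	0	0
4	0.00000000	0	0
5	0.00000000	0	0
6	0.00000000	0	0
7	0.00000000	0	0
8	0.00000000	0	0
9	0.00000000	0	0
10	0.00000000	0	0
11	0.00000000	0	0
12	0.00000000	0	0
13	0.00000000	0	0
14	0.00000000	0	0
15	0.00000000	0	0
16	0.00000000	0	0
17	0.00000000	0	0
18	0.00000000	0	0
19	0.00000000	0	0
20	0.00000000	0	0
21	0.00000000	0	0
22	0.00000000	0	0
23	0.00000000	0	0
24	0.00000000	0	0
25	0.00000000	0	0
26	0.00000000	0	0
27	0.00000000	0	0
28	0.00000000	0	0
29	0.00000000	0	0
30	0.00000000	0	0
31	0.00000000	0	0
32	0.00000000	0	0
33	0.00000000	0	0
34	0.00000000	0	0
35	0.00000000	0	0
36	0.00000000	0	0
37	0.00000000	0	0
38	0.00000000	0	0
39	0.00000000	0	0
40	0.00000000	0	0
41	0.00000000	0	0
42	0.00000000	0	0
43	0.00000000	0	0
44	0.00000000	0	0
45	0.00000000	0	0
46	0.00000000	0	0
47	0.00000000	0	0
48	0.00000000	0	0
49	0.00000000	0	0
50	0.00000000	0	0
51	0.00000000	0	0
52	0.00000000	0	0
53	0.00000000	0	0
54	0.00000000	0	0
55	0.00000000	0	0
56	0.00000000	0	0
57	0.00000000	0	0
58	0.00000000	0	0
59	0.00000000	0	0
60	0.00000000	0	0
61	0.00000000	0	0
62	0.00000000	0	0
63	0.00000000	0	0
64	0.00000000	0	0
65	0.00000000	0	0
66	0.00000000	0	0
67	0.00000000	0	0
68	0.00000000	0	0
69	0.00000000	0	0
70	0.00000000	0	0
71	0.00000000	0	0
72	0.00000000	0	0
73	0.00000000	0	0
74	0.00000000	0	0
75	0.00000000	0	0
76	0.00000000	0	0
77	0.00000000	0	0
78	0.00000000	0	0
79	0.00000000	0	0
80	0.00000000	0	0
81	0.00000000	0	0
82	0.00000000	0	0
83	0.00000000	0	0
84	0.01666667	0	1
85	1.00000000	0	59
86	1.00000000	0	0
87	1.00000000	0	0
88	1.00000000	0	0
89	1.00000000	0	0
90	1.00000000	0	0
91	1.00000000	0	0
92	1.00000000	0	0
93	1.00000000	0	0
94	1.00000000	0	0
95	1.00000000	0	0
96	1.00000000	0	0
97	1.00000000	0	0
98	1.00000000	0	0
99	1.00000000	0	0
100	1.00000000	0	0
101	1.00000000	0	0
102	1.00000000	0	0
103	1.00000000	0	0
104	1.00000000	0	0
105	1.00000000	0	0
106	1.00000000	0	0
107	1.00000000	0	0
108	1.00000000	0	0
109	1.00000000	0	0
110	1.00000000	0	0
111	1.00000000	0	0
112	1.00000000	0	0
113	1.00000000	0	0
114	1.00000000	0	0
115	1.00000000	0	0
116	1.00000000	0	0
117	1.00000000	0	0
118	1.00000000	0	0
119	1.00000000	0	0
120	1.00000000	0	0
121	1.00000000	0	0
122	1.00000000	0	0
123	1.00000000	0	0
124	1.00000000	0	0
125	1.00000000	0	0
126	1.00000000	0	0
127	1.00000000	0	0
128	1.00000000	0	0
129	1.00000000	0	0
130	1.00000000	0	0
131	1.00000000	0	0
132	1.00000000	0	0
133	1.00000000	0	0
134	1.00000000	0	0
135	1.00000000	0	0
136	1.00000000	0	0
137	1.00000000	0	0
138	1.00000000	0	0
139	1.00000000	0	0
140	1.00000000	0	0
141	1.00000000	0	0
142	1.00000000	0	0
143	1.00000000	0	0
144	1.00000000	0	0
145	1.00000000	0	0
146	1.00000000	0	0
147	1.00000000	0	0
148	1.00000000	0	0
149	1.00000000	0	0
150	1.00000000	0	0
151	1.00000000	0	0
152	1.00000000	0	0
153	1.00000000	0	0
154	1.00000000	0	0
155	1.00000000	0	0
156	1.00000000	0	0
157	1.00000000	0	0
158	1.00000000	0	0
159	1.00000000	0	0
160	1.00000000	0	0
161	1.00000000	0	0
162	1.00000000	0	0
163	1.00000000	0	0
164	1.00000000	0	0
165	1.00000000	0	0
166	1.00000000	0	0
167	1.00000000	0	0
168	1.00000000	0	0
169	1.00000000	60	0
170	0.00000000	0	0
171	0.00000000	0	0
172	0.00000000	0	0
173	0.00000000	0	0
174	0.00000000	0	0
175	0.00000000	0	0
176	0.00000000	0	0
177	0.00000000	0	0
178	0.00000000	0	0
179	0.00000000	0	0
180	0.00000000	0	0
181	0.00000000	0	0
182	0.00000000	0	0
183	0.00000000	0	0
184	0.00000000	0	0
185	0.00000000	0	0
186	0.00000000	0	0
187	0.00000000	0	0
188	0.00000000	0	0
189	0.00000000	0	0
190	0.00000000	0	0
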