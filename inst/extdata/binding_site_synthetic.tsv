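position	chain	aa	x	y	z
19	A	F	5.948	2.551	0.344
57	A	W	4.259	-6.576	2.826
150	A	Y	3.691	-0.761	3.944
225	A	V	7.824	-4.402	-0.679
228	A	A	-0.45	1.086	7.273
415	A	R	-7.516	0.256	-1.976
85	B	F	4.277	5.599	-2.014
86	B	F	2.012	-2.168	-1.156
17	A	L	8.477	2.139	-2.998
20	A	G	-2.759	-1.827	5.124
55	A	T	-5.917	-4.3	0.259
58	A	D	-4.117	5.907	3.478
148	A	S	1.197	6.294	-5.589
152	A	P	-5.105	-0.371	-5.447
223	A	A	0.259	-8.972	1.469
226	A	I	4.965	1.146	-4.793
230	A	Y	0.644	0.673	-8.975
300	A	M	4.041	7.265	1.863
302	A	N	-7.555	-0.647	5.029
413	A	E	-1.305	-6.543	5.844
417	A	K	1.661	5.299	4.843
83	B	H	0.308	6.335	-1.03
87	B	C	-0.277	-4.456	-4.326
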