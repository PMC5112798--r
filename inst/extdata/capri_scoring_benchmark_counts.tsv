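target	n_models	H	M	A	I	R
T29	2083	2	72	70	1629	310
T30	1343	0	0	2	1104	237
T32	599	0	3	12	557	27
T35	499	0	0	2	465	32
T37	1500	8	35	35	1060	362
T39	1400	0	3	1	1257	139
T40.CA	2180	90	141	123	1531	295
T40.CB	2180	86	22	26	1751	295
T41	1200	2	99	198	730	171
T46	1699	0	0	24	1297	378
T47	1051	278	301	21	388	63
T50	1451	0	35	89	1141	184
T53	1400	0	9	92	1090	209
T54	1400	0	1	18	1195	185
T72.1	914	0	0	6	659	249
T79.1	999	0	7	13	701	278
T79.2	999	0	7	56	658	278
T79.3	999	0	0	2	719	278
T86.1	1010	0	5	25	942	38
T86.2	1010	0	8	17	947	38
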