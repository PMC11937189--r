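no	compound	rt_min	ri
1	Octanal	8.67	1006
2	2,6-Dimethyl-nonane	8.96	1028
3	Borneol	11.97	1139
4	alpha-Terpineol	12.37	1174
5	Decanal	12.54	1207
6	Citral	13.60	1276
7	Copaene	15.39	1386
8	ar-Curcumene	17.57	1487
9	alpha-Zingiberene	17.89	1501
10	alpha-Farnesene	18.17	1511
11	alpha-Bisabolene	18.26	1515
12	Sesquiphellandrene	18.73	1531
13	Nerolidol	19.79	1569
14	Zingiberenol	21.10	1622
15	Zingerone	21.84	1658
16	Cedrenol	22.75	1704
17	Acorenone B	24.53	1817
18	[6]-Isoshogaol	29.24	2241
19	[6]-Paradol	29.32	2250
20	[6]-Shogaol	29.87	2312
21	Methyl-[6]-Shogaol	30.10	2337
22	[6]-Gingerdione	30.24	2354
23	[6]-Gingerol	30.74	2413
24	Diacetoxy-[6]-gingerdiol	31.46	2501
25	[8]-Shogaol	31.64	2526
26	Methyldiacetoxy-[6]-gingerdiol	31.77	2544
27	[10]-Shogaol	33.26	2747
28	[10]-Gingerdione	33.58	2793
29	Geranial acetal of [6]-gingerdiol	35.79	3116
30	beta-Sitosterol	37.50	3394
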