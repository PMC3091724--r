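case_id	total_loh	loh_cn1	loh_cn2	loh_cn34
1	31808	2260	26801	2747
2	368	0	205	163
3	377	0	139	238
4	36175	2093	27655	6427
5	24	0	0	24
6	14751	210	12661	1880
7	3559	0	2905	654
8	2408	4	2217	187
9	593	1	266	326
10	17546	1075	12087	4384
11	78159	3678	67726	6755
12	41	0	0	41
13	6113	209	5154	750
14	13498	4084	9190	224
15	3	0	3	0
16	1431	0	54	1377
17	16934	5732	10842	360
18	2107	0	1553	554
19	0	0	0	0
20	527	0	137	390
21	19954	62	16332	3560
22	11180	4410	6357	413
23	14523	5939	5953	2631
24	15773	5672	9354	747
25	23005	20	17114	5871
26	37691	21495	15229	967
27	12120	4500	6299	1321
28	494	0	37	457
29	18222	444	15400	2378
30	42499	16432	25394	673
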