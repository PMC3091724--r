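arm	total_loh	loh_cn1	loh_cn2	loh_cn34
1p	10576	2930	6522	1124
1q	8366	459	7674	233
2p	11321	371	10770	180
2q	23115	3015	18939	1161
3p	27593	15335	12064	194
3q	7256	41	4168	3047
4p	12223	4771	7452	0
4q	28105	9142	17905	1058
5p	1315	0	1259	56
5q	16537	7744	8777	16
6p	5622	342	4870	410
6q	3365	165	2773	427
7p	7389	9	5491	1889
7q	8001	151	6452	1398
8p	8803	1580	6234	989
8q	17321	47	4633	12641
9p	18292	2772	13333	2187
9q	31400	1965	27212	2223
10p	2739	472	2063	204
10q	14651	1728	12075	848
11p	9391	2367	6902	122
11q	17377	5116	10422	1839
12p	5229	156	3251	1822
12q	6794	67	5980	747
13q	35648	5897	25964	3787
14q	10931	1484	7446	2001
15q	10194	685	8313	1196
16p	1395	111	1284	0
16q	3127	1	2832	294
17p	7719	324	6939	456
17q	16328	38	14754	1536
18p	2596	488	1147	961
18q	9978	3108	6838	32
19p	1069	1	1065	3
19q	3505	932	2482	91
20p	1278	0	229	1049
20q	1773	60	1677	36
21q	9444	3825	5599	20
22q	4177	621	3334	222
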