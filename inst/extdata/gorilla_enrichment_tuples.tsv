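metabolite	category	go_id	description	p_value	enrichment	N	B	n	b
myoinositol	BP	GO:0032502	developmental process	6.40E-10	1.45	7307	1397	864	240
myoinositol	BP	GO:0030198	extracellular matrix organization	1.00E-09	7.16	7307	56	310	17
myoinositol	BP	GO:0007155	cell adhesion	1.20E-08	2.45	7307	377	412	52
myoinositol	BP	GO:0022610	biological adhesion	1.40E-08	2.44	7307	378	412	52
myoinositol	BP	GO:0043062	extracellular structure organization	2.20E-07	4.92	7307	86	311	18
myoinositol	MF	GO:0005201	extracellular matrix structural constituent	2.10E-09	7.39	7307	51	310	16
myoinositol	CC	GO:0005576	extracellular region	3.80E-21	2.76	7307	885	311	104
myoinositol	CC	GO:0044421	extracellular region part	7.10E-17	2.28	7307	513	757	121
myoinositol	CC	GO:0031012	extracellular matrix	5.30E-15	5.34	7307	159	310	36
myoinositol	CC	GO:0005578	proteinaceous extracellular matrix	2.90E-14	5.57	7307	142	305	33
myoinositol	CC	GO:0044420	extracellular matrix part	2.30E-10	3.44	7307	71	986	33
myoinositol	CC	GO:0005581	collagen	1.60E-08	21.83	7307	26	103	8
taurine	BP	GO:0032502	developmental process	8.20E-08	1.48	7307	1397	630	178
taurine	BP	GO:0048731	system development	1.90E-07	2.23	7307	314	554	53
taurine	MF	GO:0005201	extracellular matrix structural constituent	6.20E-10	16.25	7307	51	97	11
taurine	CC	GO:0044421	extracellular region part	8.30E-14	2.44	7307	513	485	83
taurine	CC	GO:0005576	extracellular region	3.90E-12	2.35	7307	885	267	76
taurine	CC	GO:0031012	extracellular matrix	2.60E-10	3.43	7307	159	482	36
taurine	CC	GO:0044420	extracellular matrix part	1.80E-09	12.73	7307	71	97	12
taurine	CC	GO:0005578	proteinaceous extracellular matrix	2.10E-09	3.52	7307	142	482	33
taurine	CC	GO:0005581	collagen	5.10E-08	9.48	7307	26	326	11
choline	BP	GO:0090304	nucleic acid metabolic process	2.00E-09	1.75	7307	497	990	118
choline	BP	GO:0022402	cell cycle process	2.30E-08	2.09	7307	239	952	65
choline	BP	GO:0007059	chromosome segregation	3.90E-07	4.65	7307	25	943	15
choline	BP	GO:0006139	nucleobase, nucleoside, nucleotide and nucleic acid metabolic process	8.80E-07	1.54	7307	640	994	134
choline	CC	GO:0044428	nuclear part	9.80E-11	1.7	7307	632	999	147
choline	CC	GO:0005634	nucleus	5.80E-09	1.3	7307	2062	990	364
choline	CC	GO:0000775	chromosome, centromeric region	2.50E-08	10.2	7307	26	303	11
glucose	BP	GO:0002376	immune system process	1.60E-09	1.83	7307	420	999	105
creatine	MF	GO:0000030	mannosyltransferase activity	5.80E-08	73.81	7307	4	99	4
glycine	CC	GO:0070469	respiratory chain	5.80E-07	4.74	7307	22	981	14
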