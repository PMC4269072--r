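chrom	start	end	label	accessibility_class	DNase_OS	FAIR_OS	H3K4me	H3K9Ac	H3K27Ac	H3K4me2
chr1	1171789	1175143	1p36.3, intergenic	equivalent	11592	8710	544.0	168.4	115.6	120.6
chr1	1181574	1185503	FAM132A:Ex1-IVS1	equivalent	7394	9695	596.5	143.0	102.8	160.9
chr1	1628792	1633615	CDK11B:IVS6	equivalent	10378	14274	326.3	222.1	121.8	177.6
chr1	1632683	1637407	CDK11B:IVS6	equivalent	12139	12829	290.7	125.8	51.8	51.8
chr1	240965538	240967390	RGS7:IVS13-IVS14	DA	1420	9976	200.6	74.0	12.1	29.6
chr1	240988582	240990678	RGS7:IVS4-IVS5	DA	2840	8999	125.3	55.3	7.4	59.2
chr4	3242502	3246008	HTT:Ex67	equivalent	9225	15222	248.0	142.8	81.4	51.8
chr5	1421588	1425427	SLC6A3:IVS4-IVS5	DA	4702	8574	172.0	80.3	66.6	14.8
chr5	9355970	9358454	SEMA5A:IVS3	DA	2827	16953	235.4	103.6	36.5	29.6
chr5	9361501	9365307	SEMA5A:IVS3	equivalent	12398	40009	3017.6	597.4	1993.0	1530.2
chr5	9371425	9374496	SEMA5A:IVS3	DA	1397	18058	531.5	48.5	81.4	59.2
chr5	11042187	11044508	CTNND2:IVS16	equivalent	2221	15462	253.7	80.3	32.6	44.4
chr5	11071700	11076039	CTNND2:IVS16	equivalent	4422	19382	344.8	158.4	118.5	77.8
chr5	11084988	11089067	CTNND2:IVS15	equivalent	2942	16403	297.3	81.4	81.4	22.2
chr5	68462247	68464721	CCNB1:Ex1-IVS3	equivalent	31707	29162	1400.2	2378.9	1953.4	2076.3
chr7	73506616	73509661	L1MK1:IVS14	equivalent	32349	30750	3473.0	4213.1	5870.8	4186.7
chr7	73534615	73536880	L1MK1:Ex1-IVS3	equivalent	3639	9068	237.2	47.3	0	22.2
chr8	116658428	116661455	TRPS1:IVS1	DA	3738	15369	650.0	224.2	78.6	396.1
chr8	116661938	116665132	TRPS1:IVS1	DA	2031	15754	316.0	112.2	59.2	57.9
chr9	213762	215844	C9orf66:Ex1	equivalent	10945	15191	868.4	1550.5	503.2	1667.6
chr9	133587757	133589963	ABL1:Ex1b-IVS1b	equivalent	32515	25514	616.8	3043.7	2278.6	1563.2
chr9	133616347	133618188	ABL1:IVS1b	equivalent	1917	10733	341.9	83.6	42.0	71.1
chr9	133733132	133735051	ABL1:IVS3	equivalent	2859	8103	188.8	50.9	74.2	37.0
chr9	133735369	133737639	ABL1:IVS3	equivalent	2211	11425	259.7	62.8	56.1	95.6
chr9	133745513	133749828	ABL1:IVS4-IVS6	equivalent	18884	37627	4959.4	477.6	982.4	998.7
chr9	133759487	133764440	ABL1:Ex11	equivalent	7053	15356	322.9	174.4	142.9	74.0
chr9	140952206	140954439	CACNA1B:Ex29-IVS31	DA	4956	8277	302.2	88.8	33.8	51.8
chr9	140969092	140971796	CACNA1B:IVS33-IVS34	DA	4127	7686	151.2	69.2	44.4	37.0
chr11	133180187	133182699	OPCML:IVS1	DA	2306	11280	202.1	77.4	37.0	133.8
chr12	11958559	11960434	ETV6:IVS2	equivalent	2403	19900	2947.6	327.2	751.8	757.8
chr12	11992883	11994726	ETV6:IVS2	equivalent	2257	16709	786.4	134.8	384.3	62.9
chr12	11992883	11995741	ETV6:IVS3	equivalent	2988	23954	887.0	206.0	453.6	232.7
chr13	100626271	100630715	13q32.3, intergenic	DA	11678	18628	216.6	76.2	65.8	23.2
chr13	100643221	100648153	13q32.3, intergenic	DA	7452	25389	687.8	115.4	83.2	221.4
chr15	22690247	22693115	15q11.2, intergenic	DA	1705	4996	347.0	85.2	47.4	29.6
chr15	22853681	22855541	TUBGCP5:IVS11-IVS13	DA	1049	21106	132.0	75.4	96.9	22.2
chr15	23864038	23868139	15q11.2, intergenic	equivalent	4260	17789	272.4	74.0	38.6	79.6
chr15	23883747	23886037	15q11.2, intergenic	equivalent	1969	6908	84.0	76.3	10.5	29.6
chr15	23886989	23890525	MAGEL2:Promoter-3′UTR	equivalent	7602	12049	198.2	88.8	51.8	50.9
chr15	25016909	25018586	15q11.2, intergenic	DA	1670	5764	216.6	38.2	48.1	111.5
chr15	25052358	25054037	15q11.2, intergenic	DA	671	6051	83.8	51.9	7.4	0
chr15	25068481	25070727	SNRPN:Promoter:IVS1	DA	1524	7291	149.1	74.4	19.3	22.2
chr15	25199392	25201602	SNRPN:IVS4	equivalent	6799	10253	258.1	1391.0	937.3	486.3
chr15	25613407	25617676	UBE3A:IVS7-IVS8	equivalent	2728	26796	3025.0	81.4	182.8	96.0
chr15	27117096	27119866	GABRA5:IVS3	DA	5815	8082	140.0	40.8	37.0	29.6
chr15	28509526	28511337	HERC2:IVS12-IVS13	DA	4580	10908	854.2	313.8	728.2	465.3
chr15	102388168	102389774	OR4F13P:IVS3-Ex5	DA	950	8872	64.0	47.6	37.0	29.6
chr16	15013674	15017156	16p13.11, intergenic	equivalent	814	9842	48.3	51.8	62.2	53.0
chr16	16412325	16415807	PKD1P1:IVS2-IVS7	equivalent	473	2681	68.0	76.8	71.4	51.8
chr16	16452359	16455837	16p13.11, intergenic	equivalent	418	6709	8.7	54.1	65.2	44.4
chr16	16234893	16236784	ABCC1:IVS30-Ex31	equivalent	4867	11513	451.2	103.6	89.3	45.6
chr16	18440574	18444056	16p12.3, intergenic	equivalent	1	1001	81.5	74.0	73.4	31.2
chr16	18484058	18487536	16p12.3, intergenic	equivalent	616	9071	67.7	89.9	51.8	19.1
chr17	905599	910582	ABR:IVS21-3′UTR	DA	10824	19481	304.9	174.9	132.8	2.9
chr17	941273	943865	ABR:IVS16	equivalent	3508	6315	170.9	89.1	74.0	71.8
chr17	2591614	2594572	CLUH:IVS25-3′UTR	equivalent	10756	11515	576.5	96.2	384.9	163.2
chr17	2596810	2599164	CLUH:IVS13-IVS19	equivalent	5323	6551	301.9	112.5	63.3	37.0
chr17	2603297	2606091	CLUH:IVS3-IVS9	equivalent	7600	7093	222.1	57.0	51.8	123.2
chr17	18128679	18133300	LLGL1:Promoter-Ex2	equivalent	36213	27618	1016.0	647.8	219.2	743.9
chr17	18143933	18146387	LLGL1:Ex17-IVS22	equivalent	7467	8690	136.8	114.2	37.0	16.8
chr17	15133018	15136902	PMP22:IVS4-Ex5	equivalent	5482	14180	207.3	113.3	60.8	34.6
chr17	15150757	15153084	PMP22:IVS3	DA	4694	12616	321.0	77.7	28.7	44.4
chr17	15174803	15176657	17p12, intergenic	DA	257	4111	63.0	89.3	37.0	31.4
chr17	15847751	15849832	ADORA2B:Promoter-Ex1	equivalent	10751	9889	763.1	241.5	79.0	980.8
chr17	15868752	15870532	ADORA2B:IVS1	DA	2859	17457	711.4	95.0	78.8	84.7
chr17	18150509	18152632	FLII:IVS15-Ex21	equivalent	23767	14999	2289.9	74.7	439.4	75.6
chr17	18153505	18154823	FLII:IVS12-IVS14	DA	3547	3937	47.1	36.7	36.8	0
chr17	19286892	19288934	MFAP4:IVS3-Ex6	equivalent	3415	5897	286.5	139.3	95.8	54.8
chr17	37861465	37863632	ERBB2:IVS5-IVS6	DA	5114	6170	296.6	90.6	78.3	84.4
chr17	37882684	37886219	ERBB2:IVS27-Ex31	equivalent	9666	16440	1561.2	617.8	331.8	836.4
chr17	38500482	38504359	RARA:IVS2	equivalent	17458	19211	3584.2	597.6	650.9	813.2
chr17	38512106	38514271	RARA:IVS8-Ex9	DA	5468	6830	177.2	130.6	125.8	88.3
chr17	38608442	38610468	IGFBP4:IVS1-IVS3	equivalent	4526	10512	230.8	39.5	29.6	62.7
chr17	38613433	38617530	IGFBP4:Ex4	equivalent	8748	18085	557.1	155.4	88.8	74.0
chr17	80290070	80293112	SECTM1:Ex1-IVS1	equivalent	13714	13008	2005.4	294.1	202.4	1002.5
chr20	10642756	10644909	JAG1:IVS2-IVS3	equivalent	2943	15006	1104.1	118.6	49.2	225.7
chr21	36259933	36264124	RUNX1:IVS2	equivalent	26119	30777	1920.4	2050.4	1478.7	2915.8
chr21	39454065	39456057	DSCR4:IVS2	equivalent	2440	7032	155.4	65.3	24.6	65.9
chr21	39463783	39466136	DSCR4:IVS2	equivalent	2017	10359	126.5	63.2	51.8	25.6
chr21	39473031	39475467	DSCR4:IVS2	equivalent	2256	10103	137.4	86.9	37.0	0.2
chr22	19338598	19342289	HIRA:IVS21-IVS24	equivalent	3429	12123	325.1	150.0	59.2	37.0
chr22	23578368	23581572	BCR:IVS1	equivalent	6792	19899	2489.1	283.0	240.2	284.8
chr22	23604414	23607814	BCR:IVS4	equivalent	11921	14381	1989.6	425.4	621.7	362.3
chr22	23623055	23625566	BCR:IVS8	equivalent	21132	16241	2543.9	311.6	501.8	451.4
chr22	51175125	51178674	ACR:Ex1-IVS3	DA	11986	12916	175.2	85.1	37.0	58.9
chrX	592626	595515	SHOX:IVS2-Ex3	DA	7316	7254	125.9	55.3	29.6	37.0
chrX	597816	600430	SHOX:IVS3	DA	6234	7821	64.0	74.0	41.5	44.4
chrX	602538	605057	SHOX:IVS5	DA	4319	4191	147.9	29.6	7.0	14.8
chrX	7891853	7895877	PNPLA4:Ex1-IVS2	equivalent	19932	42372	1854.3	2340.4	2553.7	1715.7
chrX	8440844	8443508	Xp22.31, intergenic	equivalent	1639	12112	151.2	59.2	30.0	45.5
chrX	8505855	8509075	KAL1:IVS9-IVS10	DA	4319	14875	147.9	106.6	14.8	44.4
chrX	9613498	9617784	TBL1X:IVS4	DA	4522	20294	429.2	164.6	115.6	133.7
chrX	9685383	9689409	TBL1X:Ex18	DA	3938	43044	336.8	101.4	65.5	90.3
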