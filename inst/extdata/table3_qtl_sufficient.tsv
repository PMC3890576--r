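trait	qtl	chrom	pos_cm	add	r2_pct	ci_lo	ci_hi	marker_lo	marker_hi	phys_lo	phys_hi	genes
SP3	1	1	852.0	3.2	14.8	847.3	864.6	csu222a	umc197a	257951442	262818614	141
SP3	2	3	508.0	1.9	0.6	507.2	511.1	AY111125	php15033	190454440	193733670	72
SP3	3	3	516.0	1.2	0.2	512.7	517.0	AI770795	pco067132	193638925	193733670	0
SP3	4	4	272.0	2.2	8.2	271.4	274.7	umc1964	AY110290	42102039	46621469	69
SP3	Total				42.9							
SP4	1	1	840.0	3.8	21.5	839.3	847.3	glb1	csu222a	256342909	261572322	145
SP4	Total				21.5							
SP5	1	1	840.0	2.2	2.2	839.3	847.3	glb1	csu222a	256342909	261572322	145
SP5	2	1	864.0	2.2	2.4	847.3	864.6	csu222a	umc197a	257951442	262818614	141
SP5	3	3	518.0	3.2	10.2	517.0	520.7	asg7b	bnl6.16a	190889172	196152996	138
SP5	4	4	274.0	2.1	4.3	271.4	274.7	umc1964	AY110290	42102039	46621469	69
SP5	5	7	266.0	3.2	5.9	265.3	280.5	mmp21	ufg54	121188675	129322867	172
SP5	6	7	286.0	0.8	0.4	285.4	288.9	cdo412b	umc116a	128981461	130295570	28
SP5	7	9	254.0	2.7	8.4	253.7	254.0	AW257883	umc1743	100609365	100724531	3
SP5	8	10	258.0	1.9	1.4	256.8	259.4	AY109920	AY109876	107077362	108377749	17
SP5	9	10	270.0	0.6	0.1	269.6	271.3	mmp121	AY110365	113828273	114695818	18
SP5	10	10	288.0	0.5	0.1	287.9	290.9	umc1330	umc1697	122801569	122924003	3
SP5	Total				65.5							
SP6	1	1	698.0	-2.5	1.7	693.6	699.9	mmp173	php20661	222399299	222711359	10
SP6	2	1	706.0	-0.4	0.1	703.5	706.4	bcd207a	AY110356	223974395	224078859	3
SP6	3	1	862.0	2.3	1.9	847.3	864.6	csu222a	umc197a	257951442	262818614	141
SP6	4	1	884.0	1.3	0.6	882.7	886.1	tb1	umc1431	266933205	267050083	4
SP6	5	4	210.0	0.9	0.4	189.1	211.4	mmp111	npi386a	17981907	25233582	114
SP6	6	4	226.0	2.9	5.1	225.7	228.4	umc1963	umc1652	26437539	27757462	22
SP6	7	4	414.0	2.5	6.1	411.3	414.2	umc2038	umc19	172796153	173318462	19
SP6	8	8	622.0	3.0	8.9	621.6	626.7	umc1638	umc1916	174236946	175350404	34
SP6	9	9	224.0	2.2	4.6	223.9	226.3	rz273c	umc81	27011615	27062858	2
SP6	Total				62.3							
RW	1	5	72.0	1.2	2.0	71.9	73.3	umc1523	mmp43	3320773	3727971	30
RW	2	5	80.0	0.3	0.1	74.4	83.7	bnl7.21c	jpsb239a	3320773	4383850	70
RW	3	7	290.0	1.5	13.6	288.9	298.4	umc116a	umc1713	127039567	129866479	59
RW	Total				25.4							
SL	1	1	1016.0	-2.4	9.8	1014.9	1031.8	igl1	umc2242	287881695	290146916	70
SL	Total				9.8							
SDW	1	1	864.0	0.3	10.7	847.3	864.6	csu222a	umc197a	257951442	262818614	141
SDW	2	7	534.0	-0.4	21.8	533.7	536.7	npi380	npi433	168366640	169262520	36
SDW	Total				31.4							
H2O	1	2	154.0	-0.3	6.8	153.1	154.6	umc1262a	umc1261a	13716641	14406715	20
H2O	2	4	402.0	-0.3	5.6	397.4	408.7	umc66a	umc104a	162903780	172858882	273
H2O	3	6	69.3	-0.2	2.9	70.2	70.3	umc1606	cdo1173c	9410989	21903419	132
H2O	4	7	258.0	-0.4	9.3	252.9	261.5	umc2092	umc5b	109977320	122636428	186
H2O	Total				37.0							
NEC	1	3	418.0	-0.7	11.7	416.1	423.6	asg39	BE639846	175604963	176553867	33
NEC	2	7	532.0	-0.6	4.8	518.9	532.0	umc1412	umc245	167566759	169345697	73
NEC	3	7	542.0	-0.1	0.2	540.8	543.4	mmp67	mmp25	169262253	170497141	42
NEC	4	7	588.0	- < 0.1	< 0.1	586.6	598.9	cdo938d	umc1406	170246381	170998616	39
NEC	5	7	602.0	0.6	2.1	600.4	602.9	umc2334	ufg39	170246381	170998616	39
NEC	Total				29.5							
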