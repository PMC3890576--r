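trait	qtl	chrom	pos_cm	add	r2_pct	ci_lo	ci_hi	marker_lo	marker_hi	phys_lo	phys_hi	genes
SP3	1	1	556.0	1.5	1.7	553.6	557.6	umc1748	bnlg1615	191860023	192968163	17
SP3	2	2	524.0	3.1	8.3	523.5	529.2	umc1604	bnlg1316	211345382	212352714	29
SP3	3	4	226.0	0.2	< 0.1	225.7	228.4	umc1963	umc1652	26437539	27757462	22
SP3	4	4	240.0	3.1	2.8	237.8	245.5	bnlg490	agrr301	31323581	40458411	186
SP3	5	7	252.0	4.1	13.7	249.1	252.4	umc1929	umc1787	105804341	110057749	42
SP3	6	8	464.0	4.1	15.0	460.8	464.0	bnlg1065	rz538a	165689209	166244750	20
SP3	7	9	206.0	-1.5	0.9	204.4	208.5	ufg71	mmp170b	25825748	26709137	19
SP3	8	9	222.0	4.2	7.2	220.7	223.9	psr160c	rz273c	26822048	49039937	292
SP3	Total				59.4							
SP4	1	1	834.0	6.1	21.9	833.0	839.3	chrom7	glb1	256342909	257540930	26
SP4	2	4	278.0	4.1	5.8	277.8	279.9	psr152b	nnr1	46450572	65900096	202
SP4	3	4	300.0	0.2	< 0.1	299.9	300.2	bnlg1755	mmp45	118324214	135333950	173
SP4	4	8	194.0	-3.2	6.3	191.0	194.1	mmp120	mmp72	23404908	60338399	367
SP4	Total				40.1							
SP5	1	1	690.0	-4.6	10.3	685.2	690.5	lim442	mmp189	214921545	219064269	68
SP5	2	1	838.0	8.4	34.0	833.0	839.3	chrom7	glb1	256342909	257540930	26
SP5	3	4	238.0	5.1	14.0	237.8	245.5	bnlg490	agrr301	31323581	40458411	186
SP5	Total				49.4							
SP6	1	1	690.0	-3.8	4.9	685.2	690.5	lim442	mmp189	214921545	219064269	68
SP6	2	1	714.0	-2.3	1.7	711.5	714.4	umc1128	umc1147	224265940	224970667	18
SP6	3	1	830.0	7.7	27.7	825.8	833.0	rz403	chrom7	255041502	257540930	53
SP6	4	4	238.0	5.2	14.1	237.8	245.5	bnlg490	agrr301	31323581	40458411	186
SP6	Total				44.2							
RL	1	3	452.0	-6.9	18.0	451.5	452.7	jpsb79	umc60	180725934	180867611	4
RL	Total				18.0							
RW	1	1	824.0	0.5	0.8	821.5	825.8	csu696	rz403	253570111	256342908	57
RW	2	1	846.0	0.8	1.9	839.3	847.3	glb1	csu222a	256342909	261572322	145
RW	3	5	74.0	1.3	12.6	73.3	74.4	mmp43	bnl7.21c	3727289	3810656	6
RW	4	5	412.0	1.2	11.0	410.8	413.6	umc1155	csu173	180186573	181568742	33
RW	5	7	148.0	0.7	3.7	132.0	148.5	asg34a	gta101a	14027268	14698304	10
RW	6	7	290.0	0.9	5.9	288.9	298.4	umc116a	umc1713	127039567	129866479	59
RW	7	8	194.0	-0.9	6.7	191.0	194.1	mmp120	mmp72	23404908	60338399	367
RW	Total				58.9							
SL	1	1	840.0	2.4	9.6	839.3	847.3	glb1	csu222a	256342909	261572322	145
SL	Total				9.6							
SDW	1	1	888.0	0.3	11.1	887.5	890.9	cdo122a	AY110019	263205925	270965223	186
SDW	2	4	238.0	0.3	11.9	237.8	245.5	bnlg490	agrr301	31323581	40458411	186
SDW	3	7	164.0	0.1	0.4	162.4	167.4	AY105589	npi600	17029068	21464802	82
SDW	4	7	174.0	-0.1	< 0.1	170.8	178.0	crt2	AY110473	24318258	50154299	312
SDW	5	7	184.0	0.3	1.4	183.7	184.4	uaz187	mmp26	50078806	50149169	3
SDW	Total				34.6							
H2O	1	2	370.0	-0.3	8.0	369.3	373.5	umc1079	bnlg1036	152207394	163566033	150
H2O	2	4	272.0	-0.4	8.8	271.4	274.7	umc1964	AY110290	42102039	46621469	69
H2O	3	4	300.0	-0.1	0.9	299.9	300.2	bnlg1755	mmp45	118324214	135333950	173
H2O	4	9	138.0	0.3	0.8	131.1	139.0	omt2	mmp162	15578721	18071240	91
H2O	5	9	146.0	-0.7	1.7	142.6	147.5	bnlg244	bnlg1401	18040440	18071240	0
H2O	6	9	150.0	0.6	2.0	147.5	153.0	bnlg1401	mmp77	18561278	18607113	0
H2O	7	9	164.0	0.1	0.6	162.5	170.4	mmp30	umc1698	16660671	20791656	146
H2O	Total				35.9							
SDW/SL	1	8	466.0	< 0.1	14.4	464.0	466.5	rz538a	umc1607	165636122	166188782	20
SDW/SL	Total				14.4							
BTR	1	1	672.0	-1.1	7.3	670.2	685.2	umc23a	lim442	212899665	219195665	110
BTR	2	1	836.0	1.9	20.9	833.0	839.3	chrom7	glb1	256342909	257540930	26
BTR	3	8	156.0	1.0	6.4	153.3	156.6	umc1974	psr598	16722932	18272098	35
BTR	Total				36.7							
LAT	1	8	188.0	-0.8	11.8	179.5	191.0	umc1530	mmp120	22245756	25351500	59
LAT	Total				11.8							
NEC	1	1	208.0	-0.8	19.0	205.0	208.5	lim122	umc1073	27398858	32868895	125
NEC	2	2	90.0	0.6	12.6	87.8	90.3	BE640649	npi421a	6474435	6534813	1
NEC	Total				24.0							
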