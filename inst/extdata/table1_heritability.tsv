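trait	abbreviation	unit	H2_deficient	H2_sufficient
SPAD value at leaf 3	SP3		0.80	0.67
SPAD value at leaf 4	SP4		0.77	0.70
SPAD value at leaf 5	SP5		0.80	0.80
SPAD value at leaf 6	SP6		0.75	0.64
Root length	RL	cm	0.51	0.42
Root weight	RW	g	0.66	0.50
Shoot length	SL	cm	0.35	0.28
Shoot dry weight	SDW	g	0.58	0.38
Shoot water content	H2O	%	0.65	0.65
Ratio between shoot dry weight and shoot length	SDW/SL	g cm-1	0.53	0.41
Branching at the terminal 5 cm of root	BTR		0.64	
Lateral root formation	LAT		0.55	0.58
Leaf necrosis	NEC		0.44	0.59
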