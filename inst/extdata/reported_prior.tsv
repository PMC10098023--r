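gene	rsid	ref	alt	freq_cohort	freq_ALL	sig_ALL	freq_EUR	sig_EUR	freq_EAS	sig_EAS	freq_AFR	sig_AFR	freq_AMR	sig_AMR	source	note
ABCA1	rs9282541	G	A	0.05252	0.00599	1	-	0	-	0	0.00075	1	0.04178	0	Native American populations	Allele A found mostly in Native Americans and their descendants; linked to early coronary disease and HDL-C levels
ABCG8	rs4245791	C	T	0.74806	0.84105	1	0.68986	0	0.99603	1	0.89334	1	0.80259	0	Latin American GWAS	C allele associated with LDL levels in Latin Americans
CELSR2	rs12740374	G	T	0.21511	0.19548	0	0.21272	0	0.04265	1	0.24735	0	0.20461	0	Latin American GWAS	T allele associated with LDL and total cholesterol in Latin Americans
LPL	rs1231383321	C	A	0.00194	-	0	-	0	-	0	-	0	-	0	Costa Rica severe hyperlipidemia cohort	Private variant found in one heterozygous individual
LPL	rs118204057	G	A	0.00583	0.00019	0	-	0	-	0	-	0	0.00144	0	Costa Rica severe hyperlipidemia cohort	Allele A found in Costa Ricans with severe hyperlipidemia
LPL	rs268	A	G	0.03307	0.00519	1	0.01391	0	-	0	0.00075	1	0.01152	0	Costa Rica severe hyperlipidemia cohort	Allele A found in Costa Ricans with severe hyperlipidemia
LPL	rs316	C	A	0.19455	0.15255	0	0.12027	0	0.11210	1	0.23676	0	0.14553	0	Costa Rica severe hyperlipidemia cohort	Allele A found in Costa Ricans with severe hyperlipidemia
LPL	rs328	C	G	0.07198	0.09245	0	0.13021	0	0.12202	0	0.06127	0	0.06340	0	Costa Rica Heart Study	G allele associated with lower risk of myocardial infarction
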