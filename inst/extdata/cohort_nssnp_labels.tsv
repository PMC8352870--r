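# Cancer-associated nsSNPs observed in two Southeast Asian whole-genome
# cohorts (Orang Asli and Malays), with the categorical verdicts of five
# functional-effect predictors. Labels: Del = deleterious, Tol = tolerated
# (suffix _low_con = low confidence), Prob_dam = probably damaging,
# pos_dam/Pos_dam = possibly damaging, Prob_ben = probably benign,
# Neu = neutral; empty cell = not predicted. highrisk marks the eight
# variants carried into the prioritization cascade. Partial transcription:
# 48 of the 52 published rows were recoverable. Coordinates are GRCh37.
rsid	trait	chrom	pos	gene	aa_change	sift	polyphen2	condel	provean	panther	highrisk
rs12621643	Acute lymphoblastic leukemia (childhood)	2	223917983	KCNE4	D145E	Tol	benign	Neu	Neu		0
rs13014235	Basal cell carcinoma	2	202215492	ALS2CR12	V43L	Tol	benign	Neu	Neu	Prob_ben	0
rs1050529	Basal cell carcinoma	6	31324615	HLA-B	A65T	Del_low_con	benign	Neu	Neu	Prob_ben	0
rs1126809	Basal cell carcinoma or squamous cell carcinoma	11	89017961	TYR	R402Q	Del	Prob_dam	Del	Neu	Prob_dam	1
rs11543198	Bladder cancer	15	74912328	CLK3	R78H	Tol_low_con			Neu		0
rs35273427	Breast cancer	1	120436751	ADAM30	T737A	Tol	benign	Neu	Neu	Prob_ben	0
rs6964587	Breast cancer	7	91630620	AKAP9	M463I	Del	benign	Neu	Neu		0
rs1053338	Breast cancer	3	63967900	ATXN7	K264R	Tol	benign	Neu	Neu	Prob_dam	0
rs3124765	Breast cancer	9	136328657	CACFD1	I58M	Del	Prob_dam	Del	Neu		1
rs11552449	Breast cancer	1	114448389	DCLRE1B	H61Y	Del	benign		Neu	Prob_ben	0
rs3815308	Breast cancer	19	2226676	DOT1L	G1386S	Tol_low_con	benign	Neu	Neu	Prob_ben	0
rs11205303	Breast cancer	1	149906413	MTMR11	M159V	Tol	benign		Neu		0
rs9379084	Breast cancer	6	7231843	RREB1	D1171N	Del	Prob_dam	Del	Del	Prob_dam	1
rs8050871	Breast cancer	16	71509796	ZNF19	Q218H	Del	pos_dam	Del	Neu	Prob_ben	0
rs757978	Chronic lymphocytic leukemia	2	242371101	FARP2	T260N	Del	Prob_dam	Del	Del	Prob_dam	1
rs11539086	Colorectal cancer	3	58552329	FAM107A	E141Q	Tol	Prob_dam	Del	Neu	Prob_dam	0
rs4836891	Colorectal cancer	9	125273574	OR1J2	R165Q	Tol_low_con	benign	Neu	Neu	Prob_ben	0
rs7248888	Colorectal cancer	19	46974003	PNMAL1	C97Y	Tol	benign	Neu	Neu	Prob_ben	0
rs16845107	Colorectal cancer	3	113127991	WDR52	K284N	Tol	benign		Neu	Prob_dam	0
rs3184504	Colorectal or endometrial cancer	12	111884608	SH2B3	W262R	Tol	benign	Neu	Neu	Prob_ben	0
rs1129506	Endometrial cancer	17	29646032	EVI2A	S23R	Del_low_con	benign		Neu	Pos_dam	0
rs2278868	Endometriosis or endometrial cancer (pleiotropy)	17	46262171	SKAP1	G161S	Tol	benign	Neu	Neu	Prob_ben	0
rs1229984	Esophageal cancer	4	100239319	ADH1B	H48R	Tol	benign	Neu	Neu	Prob_ben	0
rs671	Esophageal cancer	12	112241766	ALDH2	E504K	Del	pos_dam	Del	Del		0
rs2274223	Esophageal cancer	10	96066341	PLCE1	H1927R	Tol	benign	Neu	Neu	Prob_ben	0
rs3765524	Esophageal cancer and gastric cancer	10	96058298	PLCE1	T1777I	Tol	benign	Neu	Neu	Prob_ben	0
rs20541	Hodgkin's lymphoma	5	131995964	IL13	Q144R	Tol	benign	Neu	Neu		0
rs3734542	Lung cancer in ever smokers	6	26468326	BTN2A1	R378Q	Tol	benign	Neu	Neu	Prob_ben	0
rs10936600	Multiple myeloma	3	169514585	LRRC34	L286I	Del	Prob_dam	Del	Neu	Prob_dam	1
rs7193541	Multiple myeloma	16	74664743	RFWD3	I564V	Tol	benign	Neu	Neu	Prob_ben	0
rs34562254	Multiple myeloma	17	16842991	TNFRSF13B	P251L	Tol	benign	Neu	Neu	Prob_ben	0
rs1052501	Multiple myeloma	3	41925398	ULK4	A542P	Del	benign	Neu	Neu	Prob_ben	0
rs2272007	Multiple myeloma (hyperdiploidy)	3	41996136	ULK4	K39R	Tol	benign	Neu	Neu	Prob_dam	0
rs6793295	Multiple myeloma and monoclonal gammopathy	3	169518455	LRRC34	S249G	Tol	benign	Neu	Neu	Prob_ben	0
rs1801591	Non-glioblastoma glioma	15	76578762	ETFA	T171I	Del	Prob_dam	Del	Del		1
rs117744081	Non-melanoma skin cancer	7	29132279	CPVL	Y168H	Del	Prob_dam	Del	Del	Prob_ben	1
rs11170164	Non-melanoma skin cancer	12	52913668	KRT5	G138E	Del	pos_dam	Del	Del	Pos_dam	0
rs1229984	Oral cavity and pharyngeal cancer	4	100239319	ADH1B	H48R	Tol	benign	Neu	Neu	Prob_ben	0
rs1494961	Oral cavity and pharyngeal cancer	4	84374480	HELQ	V306I	Tol	benign	Neu	Neu		0
rs763780	Pancreatic cancer	6	52101739	IL17F	H161R	Tol	benign	Neu	Del	Prob_ben	0
rs2257205	Pancreatic cancer	17	56448297	RNF43	R117H	Tol	pos_dam	Neu	Neu	Pos_dam	0
rs3795244	Pancreatic cancer	17	30692396	ZNF207	A240S	Tol	benign	Neu	Neu	Prob_dam	0
rs130067	Prostate cancer	HSCHR6_MHC_MANN	31163464	CCHCR1	D275E	Tol	benign	Neu		Prob_dam	0
rs2066827	Prostate cancer	12	12871099	CDKN1B	V109D	Tol	benign	Neu	Neu	Prob_ben	0
rs2277283	Prostate cancer	11	61908440	INCENP	M506T	Del	Prob_dam	Del	Del	Prob_dam	1
rs2292884	Prostate cancer	2	238443226	MLPH	H347R	Tol	benign	Neu	Neu	Prob_ben	0
rs11071896	Testicular germ cell tumor	15	66821250	ZWILCH	S344G	Tol	benign	Neu	Neu	Prob_ben	0
rs6793295	Thyroid cancer	3	169518455	LRRC34	S249G	Tol	benign	Neu	Neu	Prob_ben	0
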