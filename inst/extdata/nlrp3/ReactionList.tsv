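!UID	!Reaction	!Reference
1	Pol_trsc_NLRP3	priming: NFkB-dependent transcription
2	Pol_trsc_IL1b	priming: NFkB-dependent transcription
3	Ribo_trsl_NLRP3	priming: translation of NLRP3 mRNA
4	Ribo_trsl_IL1b	priming: translation of pro-IL-1b mRNA
5	X_deg_NLRP3mRNA	priming: transcript turnover (placeholder catalyst X)
6	X_deg_IL1bmRNA	priming: transcript turnover (placeholder catalyst X)
7	Tbk1_P+_AKT_[(T308)]	licensing: priming-dependent AKT activation
8	Pdk1_P+_AKT_[(T308)]	licensing: constitutive AKT activation loop
9	mTORC2_P+_AKT_[(S473)]	licensing: constitutive AKT activation loop
10	PP2A_P-_AKT_[(T308)]	licensing: AKT dephosphorylation
11	X_P-_AKT_[(S473)]	licensing: unknown phosphatase (placeholder X)
12	PI3K_P+_PI_[(3)]	licensing: phosphoinositide 3-phosphorylation
13	PI4K_P+_PI_[(4)]	licensing: phosphoinositide 4-phosphorylation
14	AKT_[PH]_ppi+_PI_[head]	licensing: AKT membrane recruitment via PH domain
15	AKT_P+_NLRP3_[(S5)]	licensing: inhibitory Ser5 phosphorylation
16	PP2Aca_P-_NLRP3_[(S5)]	licensing: Ser5 dephosphorylation
17	JNK1_P+_NLRP3_[(S198)]	licensing: priming-dependent Ser198 phosphorylation
18	BRCC36_[bd]_ppi+_NLRP3_[nb36]	licensing: BRCC36 recruitment to NLRP3
19	G5_[dub]_ppi+_BRCC36_[G5]	inhibitor: G5 binding to BRCC36
20	CSNK1A1_P+_NLRP3_[(S806)]	licensing: constitutive Ser806 phosphorylation
21	X_P-_NLRP3_[(S806)]	licensing: unknown phosphatase (placeholder X)
22	uKin_P+_NLRP3_[(Y861)]	licensing: unknown kinase on Tyr861
23	PTPN22_P-_NLRP3_[(Y861)]	licensing: Tyr861 dephosphorylation
24	NEK7_[clobe]_ppi+_NLRP3_[HD2LRR]	activation: centrosomal NEK7 recruitment
25	BRCC36_ub63-_NLRP3_[(lrr)]	licensing: K63 deubiquitylation of the LRR domain
26	MCC950_[bd]_ppi+_NLRP3_[NOD]	inhibitor: MCC950 binding to the NOD
27	PKA_P+_NLRP3_[(S295)]	ATPase: Ser295 phosphorylation
28	PKD_P+_NLRP3_[(S295)]	ATPase: Ser295 phosphorylation
29	X_P-_NLRP3_[(S295)]	ATPase: unknown phosphatase (placeholder X)
30	NLRP3_aBind_NLRP3_[(NBD)]	ATPase: ATP binding to the empty NBD
31	NLRP3_aEx_NLRP3_[(NBD)]	ATPase: ADP-to-ATP exchange
32	NLRP3_aHy_NLRP3_[(NBD)]	ATPase: ATP hydrolysis
33	NLRP3_[KMKK]_ppi+_PI_[head]	trigger: PI(4)P binding via the polybasic KMKK motif
34	NLRP3_[KMKK]_ppi-_PI_[head]	trigger: membrane release in the ADP-bound state
35	NLRP3_[cl]_i_CL_[lrrCL]	trigger: cardiolipin binding via the LRR domain
36	NLRP3_[NACHT]_ppi+_NLRP3_[NACHT]	assembly: NACHT-NACHT oligomerisation
37	NLRP3_[pydA]_ppi+_NLRP3_[pydB]	assembly: NLRP3 PYD filament
38	ASC_[pydA]_ppi+_NLRP3_[pydB]	assembly: ASC nucleation on the NLRP3 PYD filament
39	ASC_[pydA]_ppi+_ASC_[pydB]	assembly: ASC PYD polymerisation (speck)
40	Caspase1_[card1]_ppi+_ASC_[card]	assembly: caspase-1 recruitment via CARD
41	Caspase1_[card1]_ppi+_Caspase1_[card2]	assembly: caspase-1 CARD filament
42	Caspase1_cut_Caspase1_[(pro)]	assembly: proximity-induced caspase-1 autoprocessing
43	Caspase1_cut_IL1b_[(pro)]	output: pro-IL-1b maturation
44	Caspase1_cut_IL18_[(pro)]	output: pro-IL-18 maturation
45	Caspase1_cut_GasderminD_[(D275)]	output: gasdermin D cleavage by caspase-1
46	Caspase4_cut_GasderminD_[(D275)]	output: gasdermin D cleavage by caspase-4
47	Caspase5_cut_GasderminD_[(D275)]	output: gasdermin D cleavage by caspase-5
48	GasderminD_[nt]_i_PI_[gdbd]	output: gasdermin D N-terminus inserts at PI lipids
49	GasderminD_[nt]_i_PS_[gdbd]	output: gasdermin D N-terminus inserts at PS lipids
50	GasderminD_[nt]_i_CL_[gdbd]	output: gasdermin D N-terminus inserts at cardiolipin
51	Caspase4_[lps]_ppi+_LPS_[lbp]	non-canonical: cytoplasmic LPS sensing by caspase-4
52	Caspase4_[dim]_ppi+_Caspase4_[dim]	non-canonical: caspase-4 dimerisation
53	Caspase4_cut_Caspase4_[(pro)]	non-canonical: caspase-4 trans-autocleavage
54	Caspase5_[lps]_ppi+_LPS_[lbp]	non-canonical: cytoplasmic LPS sensing by caspase-5
55	Caspase5_[dim]_ppi+_Caspase5_[dim]	non-canonical: caspase-5 dimerisation
56	Caspase5_cut_Caspase5_[(pro)]	non-canonical: caspase-5 trans-autocleavage
57	RNF125_ub63+_NLRP3_[(lrr)]	turnover: K63 ubiquitylation of the LRR domain
58	TRIM31_ub48+_NLRP3_[(K496)]	turnover: constitutive K48 ubiquitylation of Lys496
59	CblB_[UBA]_ppi+_NLRP3_[lrrUb]	turnover: CblB recruitment to K63 chains
60	CblB_ub48+_NLRP3_[(K496)]	turnover: CblB-mediated K48 ubiquitylation
61	Proteasome_deg_NLRP3	turnover: proteasomal degradation of NLRP3
62	SQSTM1_[UBA]_ppi+_NLRP3_[ub]	turnover: autophagy receptor binding
63	TRIM20_[bd]_ppi+_NLRP3_[t20]	turnover: precision autophagy of assembled complexes
64	TRIM20_[asc]_ppi+_ASC_[t20]	turnover: TRIM20 bridging to ASC
65	LysosomalProteases_deg_NLRP3	turnover: autophagosomal degradation of NLRP3
66	LysosomalProteases_deg_ASC	turnover: autophagosomal degradation of ASC
67	LysosomalProteases_deg_Caspase1	turnover: autophagosomal degradation of caspase-1
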