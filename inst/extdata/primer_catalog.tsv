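pair_id	provenance	length_category	target_domain	f_id	f_seq	f_first	f_last	r_id	r_seq	r_first	r_last	length_bps	region
KP_F048-OP_R043	selected	S	bacteria	KP_F048	TACGGRAGGCAGCAG	342	356	OP_R043	CCGCGRCTGCTGGCAC	514	529	187	V3-V4
OP_F098-OP_R119	selected	S	bacteria	OP_F098	CCAGCAGCYGCGGTAAN	517	533	OP_R119	GGACTACCRGGGTATCTAA	787	805	288	V4-V5
OP_F066-KP_R040	selected	S	bacteria	OP_F066	GGMTTAGATACCC	784	796	KP_R040	CCGTCAATTCMTTTGAGTTT	906	925	141	V5-V6
OP_F009-OP_R030	selected	S	bacteria	OP_F009	GGATTAGATACCCBRGTAGTC	784	804	OP_R030	TCACRRCACGAGCTGWCGAC	1060	1079	295	V5-V7
KP_F061-KP_R074	selected	S	bacteria	KP_F061	ACTCAAAKGAATWGACGG	908	925	KP_R074	GGGTYKCGCTCGTTR	1099	1113	205	V6-V7
OP_F101-OP_R030	selected	S	bacteria	OP_F101	GAATTGRCGGGGRCC	916	930	OP_R030	TCACRRCACGAGCTGWCGAC	1060	1079	163	V6-V7
OP_F053-KP_R020	selected	M	bacteria	OP_F053	GRGTTYGATYMTGGCTCAG	9	27	KP_R020	CTGCTGCCTYCCGTA	342	356	347	V1-V3
KP_F048-KP_R031	selected	M	bacteria	KP_F048	TACGGRAGGCAGCAG	342	356	KP_R031	TACHVGGGTATCTAAKCC	784	801	459	V3-V5
KP_F048-OP_R073	selected	M	bacteria	KP_F048	TACGGRAGGCAGCAG	342	356	OP_R073	CRTACTHCHCAGGYG	879	893	551	V3-V6
KP_F051-KP_R041	selected	M	bacteria	KP_F051	GTGCCAGCMGCNGCGG	514	529	KP_R041	CGTCAATTCMTTTGAGTT	907	924	410	V4-V6
KP_F051-OP_R030	selected	M	bacteria	KP_F051	GTGCCAGCMGCNGCGG	514	529	OP_R030	TCACRRCACGAGCTGWCGAC	1060	1079	565	V4-V7
OP_F116-KP_R060	selected	M	bacteria	OP_F116	YAACGAGCGCAACCC	1099	1113	KP_R060	GACGGGCGGTGWGTRCA	1390	1406	307	V7-V9
KP_F048-OP_R030	selected	L	bacteria	KP_F048	TACGGRAGGCAGCAG	342	356	OP_R030	TCACRRCACGAGCTGWCGAC	1060	1079	737	V3-V7
KP_F048-KP_R060	selected	L	bacteria	KP_F048	TACGGRAGGCAGCAG	342	356	KP_R060	GACGGGCGGTGWGTRCA	1390	1406	1064	V3-V9
KP_F056-KP_R077	selected	L	bacteria	KP_F056	AYTGGGYDTAAAGNG	572	576	KP_R077	GACGGGCGGTGTGTACAA	1389	1406	834	V4-V9
KP_F018-KP_R002	selected	S	archaea	KP_F018	GYGCASCAGKCGMGAAW	U	U	KP_R002	TTACCGCGGCKGCTG	518	532	-	V4
OP_F066-KP_R013	selected	S	archaea	OP_F066	GGMTTAGATACCC	784	796	KP_R013	GGCCATGCACCWCCTCTC	U	U	-	V5-V6
KP_F018-KP_R032	selected	M	archaea	KP_F018	GYGCASCAGKCGMGAAW	U	U	KP_R032	TACNVGGGTATCTAATCC	784	801	-	V3-V5
KP_F018-OP_R073	selected	M	archaea	KP_F018	GYGCASCAGKCGMGAAW	U	U	OP_R073	CRTACTHCHCAGGYG	879	893	-	V3-V5
KP_F020-KP_R013	selected	M	archaea	KP_F020	CAGCMGCCGCGGTAA	518	532	KP_R013	GGCCATGCACCWCCTCTC	U	U	-	V3-V6
KP_F022-KP_R063	selected	M	archaea	KP_F022	AGGAATTGGCGGGGGAGCA	U	U	KP_R063	TACCTTGTTACGACTT	1491	1506	-	V5-V9
OP_F114-KP_R013	selected	L	archaea	OP_F114	CCTAYGGGRBGCASCAG	340	356	KP_R013	GGCCATGCACCWCCTCTC	U	U	-	V3-V6
KP_F018-KP_R063	selected	L	archaea	KP_F018	GYGCASCAGKCGMGAAW	U	U	KP_R063	TACCTTGTTACGACTT	1491	1506	-	V3-V9
OP_F066-OP_R016	selected	L	archaea	OP_F066	GGMTTAGATACCC	784	796	OP_R016	CGGTGTGTGCAAGGAG	U	U	-	V5-V9
OP_F114-KP_R002	selected	S	both	OP_F114	CCTAYGGGRBGCASCAG	340	356	KP_R002	TTACCGCGGCKGCTG	518	532	192	V3-V4
KP_F020-KP_R032	selected	S	both	KP_F020	CAGCMGCCGCGGTAA	518	532	KP_R032	TACNVGGGTATCTAATCC	784	801	283	V4-V5
OP_F066-OP_R073	selected	S	both	OP_F066	GGMTTAGATACCC	784	796	OP_R073	CRTACTHCHCAGGYG	879	893	109	V5-V6
OP_F114-KP_R031	selected	M	both	OP_F114	CCTAYGGGRBGCASCAG	340	356	KP_R031	TACHVGGGTATCTAAKCC	784	801	461	V3-V5
OP_F114-OP_R073	selected	M	both	OP_F114	CCTAYGGGRBGCASCAG	340	356	OP_R073	CRTACTHCHCAGGYG	879	893	553	V3-V6
KP_F020-OP_R073	selected	M	both	KP_F020	CAGCMGCCGCGGTAA	518	532	OP_R073	CRTACTHCHCAGGYG	879	893	375	V4-V6
OP_F114-OP_R121	selected	L	both	OP_F114	CCTAYGGGRBGCASCAG	340	356	OP_R121	ACGGGCGGTGWGTRC	1391	1405	1065	V3-V9
KP_F020-OP_R121	selected	L	both	KP_F020	CAGCMGCCGCGGTAA	518	532	OP_R121	ACGGGCGGTGWGTRC	1391	1405	887	V4-V9
OP_F066-OP_R121	selected	L	both	OP_F066	GGMTTAGATACCC	784	796	OP_R121	ACGGGCGGTGWGTRC	1391	1405	621	V5-V9
KP_F078-OP_R010	most_used	S	both	KP_F078	GTGCCAGCMGCCGCGGTAA	514	532	OP_R010	GGACTACHVGGGTWTCTAAT	786	805	291	V4-V5
KP_F031-KP_R021	most_used	M	bacteria	KP_F031	AGAGTTTGATCCTGGCTCAG	8	27	KP_R021	TTACCGCGGCTGCTGGCAC	515	532	524	V1-V4
KP_F047-KP_R035	most_used	M	bacteria	KP_F047	CCTACGGGNGGCWGCAG	340	356	KP_R035	GACTACHVGGGTATCTAATCC	784	804	464	V3-V5
OP_F009-OP_R029	most_used	M	bacteria	OP_F009	GGATTAGATACCCBRGTAGTC	784	868	OP_R029	ACGTCRTCCCCDCCTTCCTC	1174	1193	409	V5-V8
KP_F014-KP_R011	most_used	L	archaea	KP_F014	TCCAGGCCCTACGGG	U	U	KP_R011	YCCGGCGTTGAMTCCAATT	U	U	-	V3-V6
KP_F034-KP_R065	most_used	L	bacteria	KP_F034	AGAGTTTGATCMTGGCTCAG	8	27	KP_R065	TACGGYTACCTTGTTACGACTT	1491	1512	1504	V1-V9
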