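sample_id	bethesda	gsc_call	histology	histology_class	alterations
N001	unknown	benign	BFN	benign	EIF1AX:p.G8R
N002	unknown	benign	BFN	benign	TSHR:p.I486M
N003	unknown	benign	BFN	benign	TSHR:p.L512R
N004	unknown	benign	BFN	benign	TSHR:p.M453T
N005	unknown	benign	BFN	benign	
N006	unknown	benign	BFN	benign	
N007	unknown	benign	BFN	benign	
N008	unknown	benign	BFN	benign	
N009	unknown	benign	BFN	benign	
N010	unknown	benign	BFN	benign	
N011	unknown	benign	BFN	benign	
N012	unknown	benign	BFN	benign	
N013	unknown	benign	BFN	benign	
N014	unknown	benign	BFN	benign	
N015	unknown	benign	BFN	benign	
N016	unknown	benign	BFN	benign	
N017	unknown	benign	BFN	benign	
N018	unknown	benign	BFN	benign	
N019	unknown	benign	BFN	benign	
N020	unknown	benign	BFN	benign	
N021	unknown	benign	BFN	benign	
N022	unknown	benign	BFN	benign	
N023	unknown	benign	BFN	benign	
N024	unknown	benign	BFN	benign	
N025	unknown	benign	BFN	benign	
N026	unknown	benign	BFN	benign	
N027	unknown	benign	BFN	benign	
N028	unknown	benign	BFN	benign	
N029	unknown	benign	BFN	benign	
N030	unknown	benign	BFN	benign	
N031	unknown	benign	BFN	benign	
N032	unknown	benign	BFN	benign	
N033	unknown	benign	BFN	benign	
N034	unknown	benign	BFN	benign	
N035	unknown	benign	BFN	benign	
N036	unknown	benign	BFN	benign	
N037	unknown	benign	BFN	benign	
N038	unknown	benign	BFN	benign	
N039	unknown	suspicious	BFN	benign	HRAS:p.Q61R
N040	unknown	suspicious	BFN	benign	HRAS:p.Q61R
N041	unknown	suspicious	BFN	benign	NRAS:p.Q61K
N042	unknown	suspicious	BFN	benign	NRAS:p.Q61R
N043	unknown	suspicious	BFN	benign	
N044	unknown	suspicious	BFN	benign	
N045	unknown	suspicious	BFN	benign	
N046	unknown	suspicious	BFN	benign	
N047	unknown	suspicious	BFN	benign	
N048	unknown	suspicious	BFN	benign	
N049	unknown	suspicious	BFN	benign	
N050	unknown	benign	HN	benign	TSHR:p.I568T
N051	unknown	benign	HN	benign	
N052	unknown	benign	HN	benign	
N053	unknown	benign	HN	benign	
N054	unknown	benign	HN	benign	
N055	unknown	benign	FA	benign	GNAS:p.Q870H
N056	unknown	benign	FA	benign	SPOP:p.P94R
N057	unknown	benign	FA	benign	SPOP:p.P94R
N058	unknown	benign	FA	benign	SPOP:p.P94R
N059	unknown	benign	FA	benign	TSHR:p.D633Y
N060	unknown	benign	FA	benign	TSHR:p.L629F
N061	unknown	benign	FA	benign	
N062	unknown	benign	FA	benign	
N063	unknown	benign	FA	benign	
N064	unknown	benign	FA	benign	
N065	unknown	benign	FA	benign	
N066	unknown	benign	FA	benign	
N067	unknown	benign	FA	benign	
N068	unknown	benign	FA	benign	
N069	unknown	benign	FA	benign	
N070	unknown	benign	FA	benign	
N071	unknown	benign	FA	benign	
N072	unknown	benign	FA	benign	
N073	unknown	benign	FA	benign	
N074	unknown	benign	FA	benign	
N075	unknown	benign	FA	benign	
N076	unknown	benign	FA	benign	
N077	unknown	benign	FA	benign	
N078	unknown	benign	FA	benign	
N079	unknown	benign	FA	benign	
N080	unknown	benign	FA	benign	
N081	unknown	benign	FA	benign	
N082	unknown	benign	FA	benign	
N083	unknown	benign	FA	benign	
N084	unknown	benign	FA	benign	
N085	unknown	benign	FA	benign	
N086	unknown	benign	FA	benign	
N087	unknown	benign	FA	benign	
N088	unknown	benign	FA	benign	
N089	unknown	benign	FA	benign	
N090	unknown	benign	FA	benign	
N091	unknown	benign	FA	benign	
N092	unknown	suspicious	FA	benign	HRAS:p.Q61R
N093	unknown	suspicious	FA	benign	NRAS:p.Q61R
N094	unknown	suspicious	FA	benign	NRAS:p.Q61R
N095	unknown	suspicious	FA	benign	NRAS:p.Q61R
N096	unknown	suspicious	FA	benign	PAX8/PPARG
N097	unknown	suspicious	FA	benign	
N098	unknown	suspicious	FA	benign	
N099	unknown	suspicious	FA	benign	
N100	unknown	suspicious	FA	benign	
N101	unknown	suspicious	FA	benign	
N102	unknown	suspicious	FA	benign	
N103	unknown	suspicious	FA	benign	
N104	unknown	suspicious	FA	benign	
N105	unknown	suspicious	FA	benign	
N106	unknown	suspicious	FA	benign	
N107	unknown	suspicious	FA	benign	
N108	unknown	suspicious	FA	benign	
N109	unknown	benign	FT-UMP	benign	
N110	unknown	benign	FT-UMP	benign	
N111	unknown	benign	FT-UMP	benign	
N112	unknown	benign	FT-UMP	benign	
N113	unknown	suspicious	FT-UMP	benign	HRAS:p.Q61R
N114	unknown	suspicious	FT-UMP	benign	NRAS:p.Q61R
N115	unknown	suspicious	FT-UMP	benign	SPOP:p.P94R
N116	unknown	suspicious	FT-UMP	benign	
N117	unknown	suspicious	FT-UMP	benign	
N118	unknown	benign	WDT-UMP	benign	
N119	unknown	benign	WDT-UMP	benign	
N120	unknown	benign	WDT-UMP	benign	
N121	unknown	benign	WDT-UMP	benign	
N122	unknown	suspicious	WDT-UMP	benign	HRAS:p.Q61R
N123	unknown	suspicious	WDT-UMP	benign	HRAS:p.Q61R
N124	unknown	suspicious	WDT-UMP	benign	NRAS:p.Q61R
N125	unknown	suspicious	WDT-UMP	benign	PAX8/PPARG
N126	unknown	benign	HCA	benign	EIF1AX:p.G9D
N127	unknown	benign	HCA	benign	PTEN:p.G129R
N128	unknown	benign	HCA	benign	TSHR:p.L629F, EZH1:p.Y642F
N129	unknown	benign	HCA	benign	TSHR:p.S425I
N130	unknown	benign	HCA	benign	
N131	unknown	benign	HCA	benign	
N132	unknown	benign	HCA	benign	
N133	unknown	benign	HCA	benign	
N134	unknown	benign	HCA	benign	
N135	unknown	benign	HCA	benign	
N136	unknown	suspicious	HCA	benign	NRAS:p.Q61K
N137	unknown	suspicious	HCA	benign	NRAS:p.Q61K
N138	unknown	suspicious	HCA	benign	TSHR:p.M453T
N139	unknown	suspicious	HCA	benign	TSHR:p.S281I
N140	unknown	suspicious	HCA	benign	
N141	unknown	suspicious	HCA	benign	
N142	unknown	suspicious	HCA	benign	
N143	unknown	benign	CLT	benign	
N144	unknown	suspicious	CLT	benign	
N145	unknown	suspicious	HTA	benign	PAX8/GLIS3
N146	unknown	benign	PTC	malignant	
N147	unknown	benign	PTC	malignant	
N148	unknown	suspicious	PTC	malignant	BRAF:p.V600E
N149	unknown	suspicious	PTC	malignant	BRAF:p.V600E
N150	unknown	suspicious	PTC	malignant	BRAF:p.V600E
N151	unknown	suspicious	PTC	malignant	NRAS:p.Q61R
N152	unknown	suspicious	PTC	malignant	SPOP:p.P94R
N153	unknown	suspicious	PTC	malignant	MKRN1/BRAF
N154	unknown	suspicious	PTC	malignant	ETV6/NTRK3
N155	unknown	suspicious	PTC	malignant	
N156	unknown	suspicious	PTC	malignant	
N157	unknown	suspicious	PTC	malignant	
N158	unknown	suspicious	PTC	malignant	
N159	unknown	suspicious	PTC	malignant	
N160	unknown	suspicious	PTC	malignant	
N161	unknown	suspicious	PTC-TCV	malignant	
N162	unknown	benign	FVPTC	malignant	
N163	unknown	suspicious	FVPTC	malignant	HRAS:p.Q61R
N164	unknown	suspicious	FVPTC	malignant	KRAS:p.Q61R, EIF1AX:p.A113_splice
N165	unknown	suspicious	FVPTC	malignant	NRAS:p.Q61K
N166	unknown	suspicious	FVPTC	malignant	NRAS:p.Q61R
N167	unknown	suspicious	FVPTC	malignant	NRAS:p.Q61R
N168	unknown	suspicious	FVPTC	malignant	NRAS:p.Q61R
N169	unknown	suspicious	FVPTC	malignant	NRAS:p.Q61R
N170	unknown	suspicious	FVPTC	malignant	
N171	unknown	suspicious	FVPTC	malignant	
N172	unknown	suspicious	FVPTC	malignant	
N173	unknown	benign	HCC-c	malignant	TSHR:p.I568T
N174	unknown	suspicious	HCC-c	malignant	EIF1AX:p.A113_splice
N175	unknown	suspicious	HCC-c	malignant	NRAS:p.Q61R
N176	unknown	suspicious	HCC-c	malignant	
N177	unknown	suspicious	HCC-c	malignant	
N178	unknown	suspicious	HCC-c	malignant	
N179	unknown	suspicious	HCC-c	malignant	
N180	unknown	suspicious	HCC-c	malignant	
N181	unknown	suspicious	HCC-c	malignant	
N182	unknown	suspicious	FC	malignant	BRAF:p.K601E
N183	unknown	suspicious	FC	malignant	HRAS:p.G13R
N184	unknown	suspicious	FC	malignant	NRAS:p.Q61R
N185	unknown	suspicious	FC	malignant	
N186	unknown	suspicious	FC	malignant	
N187	unknown	suspicious	FC	malignant	
N188	unknown	suspicious	FC	malignant	
N189	unknown	suspicious	PDTC	malignant	NRAS:p.Q61K
N190	unknown	suspicious	MTC	malignant	HRAS:p.Q61R
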