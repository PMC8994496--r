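module	p	occurrence	n_target_genes	target_genes
SP1F_SP1F_06	0.002	30	14	PGF,GADD45A,SLC16A6,ADAMTS9,CYP1A1,SLC2A8,SDC4,PMP22,TUBB3,IFRD1,HYAL2,ATF3,HES6,HEYL
NFKB_SP1F_03	0.002	12	8	SLC2A8,SDC4,MYLK4,PGF,LRP4,PMP22,HEYL,CEBPD
SP1F_ETSF_04	0.087	8	8	ABRA,SDC4,PGF,LCAT,PMP22,CYP1A1,SMAD7,HES6
SMAD_E2FF_01	0.088	12	7	SLC2A8,SDC4,IFRD1,PDK4,CEBPD,HES6,FOS
SP1F_YY1F_01	0.044	10	7	PGF,ABRA,GEM,SDC4,SLC2A8,ATF3,HES6
SP1F_CAAT_02	0.039	6	5	SDC4,PFKFB3,IFRD1,PMP22,HES6
SP1F_EBOX_SP1F_01	0.085	4	4	MYLK4,PMP22,PDK4,CEBPD
RUSH_EGRF_01	0.049	3	3	SDC4,GADD45A,SPOCK2
IRFF_NFAT_01	0.084	3	3	MYLK4,ADAMTS9,IFRD1
GATA_GATA_GATA_01	0.013	4	2	SLC16A6,ADAMTS9
MYOD_MYOD_03	0.066	3	2	SPOCK2,HES6
AP1F_ETSF_04	0.013	2	2	IFRD1,HYAL2
YY1F_SRFF_02	0.028	2	2	ATF3,FOS
ZFHX_ZFHX_NKXH_01	0.037	2	2	GADD45A,ADAMTS9
SMAD_HIFF_01	0.032	2	1	PFKFB3
SP1F_MZF1_01	0.035	2	1	PMP22
ETSF_SP1F_SMAD_01	0.016	1	1	HEYL
SRFF_AP1F_01	0.024	1	1	FOS
YY1F_SRFF_01	0.039	1	1	FOS
PAX8_NKXH_01	0.039	1	1	PMP22
ETSF_SRFF_01	0.047	1	1	FOS
MEF2_MYOD_01	0.054	1	1	SLC16A6
KLFS_CREB_KLFS_01	0.070	1	1	SLC2A8
CAAT_SREB_01	0.077	1	1	IFRD1
GATA_HNF1_02	0.077	1	1	PDK4
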