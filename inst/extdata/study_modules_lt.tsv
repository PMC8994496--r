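module	p	occurrence	n_target_genes	target_genes
ETSF_ETSF_01	0.076	16	15	IL16,SERPINE1,HES1,HSPBAP1,CDIPT,XYLT2,TUBB3,THBS1,MED23,GPAM,PIGM,CEBPD,HEYL,HES6,MYOD1
SP1F_CAAT_02	0.040	10	9	NME6,SDC4,PDPR,HES6,PFKFB3,CDIPT,PMP22,THBS1,IFRD1
CAAT_AP1F_01	0.035	8	8	SLC25A25,SERPINE1,NME6,IMP3,HSPBAP1,SLC2A3,THBS1,ATF3
SP1F_EBOX_SP1F_01	0.024	8	7	DFFB,GLUL,PDK4,IMP3,PMP22,XYLT2,CEBPD
CAAT_SP1F_01	0.088	5	5	SERPINE1,ATP1B1,GLUL,GEM,HES6
GATA_GATA_GATA_01	0.037	5	3	NME6,SLC16A6,MED23
YY1F_SRFF_02	0.016	3	3	SLC2A3,ATF3,FOS
SORY_SORY_EGRF_01	0.061	3	3	MUSK,ATP1B1,RAB3IL1
NFKB_NFKB_01	0.064	3	3	SLC25A25,GLUL,GEM
HNF1_GATA_01	0.098	3	3	MED23,PLD1,ATP1B1
KLFS_NR2F_KLFS_01	0.024	3	2	SERPINE1,TUBB3
STAF_SP1F_01	0.026	2	2	GLUL,HEYL
RXRF_EBOX_01	0.043	2	2	PDPR,RAB3IL1
AP1F_SMAD_01	0.055	2	2	IL16,THBS1
ETSF_AP1F_04	0.067	2	2	ACOT11,HSPBAP1
CEBP_MYBL_03	0.076	2	2	ACOT11,HSPBAP1
AARF_CEBP_01	0.091	2	2	ABRA,NME6
BRNF_RXRF_02	0.066	4	1	DLL4
NFKB_ETSF_01	0.007	2	1	DLL4
SRFF_AP1F_01	0.047	1	1	FOS
ETSF_SP1F_SMAD_01	0.062	1	1	HEYL
YY1F_SRFF_01	0.076	1	1	FOS
PAX8_NKXH_01	0.076	1	1	PMP22
ETSF_SRFF_01	0.091	1	1	FOS
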