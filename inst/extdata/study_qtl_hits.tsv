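gene	qtl_id	trait	trait_class
CDIPT	QTL_SF	Shear force	meat-quality
CEBPD	QTL_SF	Shear force	meat-quality
DNAJB4	QTL_SF	Shear force	meat-quality
GPAM	QTL_SF	Shear force	meat-quality
RAB3IL1	QTL_SF	Shear force	meat-quality
MAPK1	QTL_SF	Shear force	meat-quality
TLR4	QTL_SF	Shear force	meat-quality
ADRB2	QTL_MC	Muscle compression	meat-quality
ADRB2	QTL_TS	Tenderness score	meat-quality
CDIPT	QTL_TS	Tenderness score	meat-quality
RAB3IL1	QTL_TS	Tenderness score	meat-quality
IFNG	QTL_TS	Tenderness score	meat-quality
DLL4	QTL_PH	Muscle pH	meat-quality
ERBB2	QTL_PH	Muscle pH	meat-quality
ATP1B1	QTL_JU	Juiciness	meat-quality
DFFB	QTL_JU	Juiciness	meat-quality
RAB3IL1	QTL_JU	Juiciness	meat-quality
SELE	QTL_JU	Juiciness	meat-quality
CEBPD	QTL_MA	Marbling	meat-quality
DLL4	QTL_MA	Marbling	meat-quality
ERBB2	QTL_MA	Marbling	meat-quality
GADD45A	QTL_MA	Marbling	meat-quality
ICAM1	QTL_MA	Marbling	meat-quality
IL1B	QTL_MA	Marbling	meat-quality
IL6	QTL_MA	Marbling	meat-quality
LEAP2	QTL_MA	Marbling	meat-quality
MYF6	QTL_MA	Marbling	meat-quality
PDK4	QTL_MA	Marbling	meat-quality
PMP22	QTL_MA	Marbling	meat-quality
SMAD7	QTL_MA	Marbling	meat-quality
TNF	QTL_MA	Marbling	meat-quality
CEBPD	QTL_MS	Marbling score	carcass
DLL4	QTL_MS	Marbling score	carcass
DNAJB4	QTL_MS	Marbling score	carcass
GADD45A	QTL_MS	Marbling score	carcass
LEAP2	QTL_MS	Marbling score	carcass
MYF6	QTL_MS	Marbling score	carcass
PDK4	QTL_MS	Marbling score	carcass
PIGM	QTL_MS	Marbling score	carcass
PMP22	QTL_MS	Marbling score	carcass
RAB3IL1	QTL_MS	Marbling score	carcass
SMAD7	QTL_MS	Marbling score	carcass
ADRB2	QTL_FA1	Monounsaturated fatty acid content	fatty-acid
ADRB2	QTL_FA2	Conjugated linoleic acid content	fatty-acid
LCAT	QTL_FA3	Omega-6 to omega-3 fatty acid ratio	fatty-acid
LCAT	QTL_FA4	Palmitic acid content	fatty-acid
GADD45A	QTL_FA5	trans-11 cis-15-C18:2 fatty acid content	fatty-acid
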