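GO:0030518	Intracellular steroid hormone receptor signaling pathway	EP300	PHB	SMARCA4	KAT5	UBE2I	SRC	CCNE1	PARK7	TRIM68	TADA3	CALR	PIAS1	NR0B1	RB1	UBE3A	NCOA6	CTNNB1	RNF4	GRIP1	MED24	RAN	MED1	FKBP4	NCOA2	SIRT1	SKP2	FHL2	BRCA1	CDK7	KDM3A	NCOA3	RNF6	NCOA4	DAXX	PMEPA1	PIAS2	HDAC1	AR	NCOA1	NR0B2	RNF14	FOXA1	TGFB1I1
GO:0030521	Androgen receptor signaling pathway	EP300	PHB	SMARCA4	KAT5	CCNE1	PARK7	TRIM68	PIAS1	RB1	UBE3A	CTNNB1	RNF4	MED24	GRIP1	RAN	MED1	FKBP4	NCOA2	SIRT1	FHL2	BRCA1	CDK7	KDM3A	NCOA3	RNF6	NCOA4	PMEPA1	DAXX	PIAS2	HDAC1	AR	NR0B2	NCOA1	RNF14	TGFB1I1
hsa00140	Steroid hormone biosynthesis	AKR1D1	CYP3A7	CYP3A5	AKR1C1	SRD5A2	AKR1C3	SRD5A1	CYP3A4
hsa04114	Oocyte meiosis	AR	YWHAQ	PPP1CA	MAPK1	PRKACA	CCNE1	CALM1
hsa04914	Progesterone-mediated oocyte maturation	HSP90AA1	CDC25B	AKT1	MAPK1	PRKACA	RAF1
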