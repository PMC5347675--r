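gene_a	gene_b
AR	EP300
AR	HDAC1
AR	NCOA1
AR	NCOA2
AR	NCOA3
AR	SRC
AR	PIAS1
AR	PIAS2
AR	FKBP4
AR	BRCA1
AR	CTNNB1
AR	DAXX
AR	SIRT1
AR	RNF6
AR	RNF14
AR	TGFB1I1
AR	FHL2
AR	MED1
AR	GRIP1
AR	CALR
AR	UBE3A
AR	RB1
AR	SMARCA4
AR	KAT5
AR	PHB
AR	PARK7
AR	TRIM68
AR	NR0B1
AR	NR0B2
AR	PMEPA1
AR	KDM3A
AR	CDK7
AR	CCNE1
AR	MAPK1
AR	PRKACA
SRD5A1	AKR1C1
SRD5A1	AKR1C3
SRD5A2	AKR1D1
CYP3A4	CYP3A5
CYP3A4	CYP3A7
CYP3A4	PPP1CA
AKR1D1	AKR1C1
EP300	HDAC1
NCOA1	NCOA2
KCNJ8	ABCC9
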