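drug	gene	evidence
FINASTERIDE	SRD5A1	synthetic
FINASTERIDE	SRD5A2	synthetic
FINASTERIDE	AR	synthetic
FINASTERIDE	CYP3A4	synthetic
FINASTERIDE	AKR1D1	synthetic
MINOXIDIL	KCNJ8	synthetic
MINOXIDIL	ABCC9	synthetic
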