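list_name	gene
SMG_demo	APC
SMG_demo	PIK3CA
SMG_demo	ARID1A
SMG_demo	ATM
SMG_demo	MTOR
SMG_demo	MSH3
SMG_demo	NOTCH1
SMG_demo	THBS1
SMG_demo	RIN1
SMG_demo	TP53
SMG_demo	KRAS
SMG_demo	MSH2
SMG_demo	MLH1
SMG_demo	MSH6
SMG_demo	PMS2
SMG_demo	PTEN
SMG_demo	SMAD4
SMG_demo	BRAF
SMG_demo	EGFR
SMG_demo	RB1
SMG_demo	VHL
SMG_demo	CDKN2A
SMG_demo	NRAS
SMG_demo	FBXW7
SMG_demo	CTNNB1
WNT_pathway	APC
WNT_pathway	CTNNB1
WNT_pathway	AXIN1
WNT_pathway	AXIN2
WNT_pathway	TCF7L2
WNT_pathway	FBXW7
PI3K_pathway	PIK3CA
PI3K_pathway	PTEN
PI3K_pathway	AKT1
PI3K_pathway	MTOR
PI3K_pathway	PIK3R1
PI3K_pathway	TSC1
PI3K_pathway	TSC2
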