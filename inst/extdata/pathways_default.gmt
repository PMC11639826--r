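cell_cycle	na	CDKN2A	CDK4	CDK6	CCND1	CCNE1	RB1
hippo	na	NF2	LATS1	LATS2	FAT1
myc	na	MYC	MYCN	MYCL	MAX
notch	na	NOTCH1	NOTCH2	NOTCH3	NOTCH4	FBXW7	CREBBP
oxidative_stress_nrf2	na	NFE2L2	KEAP1	CUL3
pi3k	na	PIK3CA	PIK3R1	PTEN	AKT1	MTOR	TSC1	TSC2	STK11
rtk_ras_map	na	EGFR	KRAS	NRAS	HRAS	BRAF	MAP2K1	ALK	ERBB2	MET	RET	ROS1	NF1
tgf_beta	na	SMAD4	SMAD2	SMAD3	TGFBR1	TGFBR2
p53	na	TP53	MDM2	MDM4	ATM
beta_catenin_wnt	na	CTNNB1	APC	AXIN1	AXIN2	TCF7L2
ddr	na	BRCA2	BRCA1	ATM	ATR	CHEK1	CHEK2	PALB2	RAD51	MLH1	MSH2	MSH6	PMS2	POLE	ERCC2	FANCA
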