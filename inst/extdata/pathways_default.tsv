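pathway	gene	role
cell_cycle	CCND1	oncogene
cell_cycle	CDK4	oncogene
cell_cycle	CDK6	oncogene
cell_cycle	RB1	suppressor
cell_cycle	CDKN2A	suppressor
hippo	YAP1	oncogene
hippo	TAZ	oncogene
hippo	NF2	suppressor
hippo	LATS1	suppressor
myc	MYC	oncogene
myc	MYCN	oncogene
myc	MXD1	suppressor
myc	MNT	suppressor
notch	NOTCH1	oncogene
notch	NOTCH2	oncogene
notch	SPEN	suppressor
notch	NCOR1	suppressor
nrf2	NFE2L2	oncogene
nrf2	KEAP1	suppressor
nrf2	CUL3	suppressor
pi3k	PIK3CA	oncogene
pi3k	AKT1	oncogene
pi3k	PTEN	suppressor
pi3k	TSC1	suppressor
rtk_ras	EGFR	oncogene
rtk_ras	ERBB2	oncogene
rtk_ras	KRAS	oncogene
rtk_ras	NF1	suppressor
tgf_beta	TGFBR1	oncogene
tgf_beta	TGFBR2	suppressor
tgf_beta	SMAD4	suppressor
p53	MDM2	oncogene
p53	MDM4	oncogene
p53	TP53	suppressor
p53	ATM	suppressor
wnt	CTNNB1	oncogene
wnt	APC	suppressor
wnt	AXIN1	suppressor
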