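component	bait_accession	match_species	protein	accession	found
CLK	O61735	Dp	CLK	A0A212EGJ4	yes
CLK	O61735	Mm	CLOCK	O08785	no
CYC	O61734	Dp	CYC	A0A212EKE6	yes
CYC	O61734	Mm	ARNTL	Q9WTL8	yes
CYC	O61734	Mm	ARNTL2	Q2VPD4	yes
TIM	P49021	Dp	TIM	A0A212ETU4	yes
PER	P07663	Dp	PER	A0A212F9R2	yes
PER	P07663	Mm	PER1	O35973	yes
PER	P07663	Mm	PER2	O54943	yes
PER	P07663	Mm	PER3	O70361	yes
CRY1	O77059	Dp	CRY1	A0A212EI23	yes
CRY2	A0A212FAM3	Mm	CRY1	P97784	yes
CRY2	A0A212FAM3	Mm	CRY2	Q9R194	yes
PDP1e	Q8SZT1	Mm	DBP	Q60925	yes
PDP1e	Q8SZT1	Mm	HLF	Q8BW74	yes
PDP1e	Q8SZT1	Mm	TEF	Q9JLC6	yes
VRI	Q9VMS4	Mm	NFIL3	O08750	yes
REV-ERBa	Q3UV55	Dm	EIP75B	P13055	yes
RORa	P51448	Dm	HR3	P31396	yes
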