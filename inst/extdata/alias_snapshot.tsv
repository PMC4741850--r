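raw	official	locus_type
APTX	APTX	protein-coding
BRCA1	BRCA1	protein-coding
NEIL3	NEIL3	protein-coding
EFCAB6	EFCAB6	protein-coding
CYP1B1	CYP1B1	protein-coding
PAPSS2	PAPSS2	protein-coding
TSC1	TSC1	protein-coding
BGLAP	BGLAP	protein-coding
FANCL	FANCL	protein-coding
MSH3	MSH3	protein-coding
ATP6V0A2	ATP6V0A2	protein-coding
RAD54L2	RAD54L2	protein-coding
NRIP1	NRIP1	protein-coding
MBD5	MBD5	protein-coding
CTBP1	CTBP1	protein-coding
SCN11A	SCN11A	protein-coding
ALG6	ALG6	protein-coding
HSD3B1	HSD3B1	protein-coding
FBXW7	FBXW7	protein-coding
PALB2	PALB2	protein-coding
FANCA	FANCA	protein-coding
BLM	BLM	protein-coding
CRISP3	CRISP3	protein-coding
TGIF1	TGIF1	protein-coding
KDR	KDR	protein-coding
ELAC2	ELAC2	protein-coding
MYH14	MYH14	protein-coding
ALG13	ALG13	protein-coding
UBE2D3	UBE2D3	protein-coding
TLN1	TLN1	protein-coding
PIAS3	PIAS3	protein-coding
AKR1C1	AKR1C1	protein-coding
DDB2	DDB2	protein-coding
ACACA	ACACA	protein-coding
HDAC9	HDAC9	protein-coding
MGAT2	MGAT2	protein-coding
TP53BP1	TP53BP1	protein-coding
IDE	IDE	protein-coding
NCOR2	NCOR2	protein-coding
GSTA1	GSTA1	protein-coding
UBE2V2	UBE2V2	protein-coding
ASXL1	ASXL1	protein-coding
SP1	SP1	protein-coding
B3GAT3	B3GAT3	protein-coding
DOLK	DOLK	protein-coding
FLT3	FLT3	protein-coding
SULT1E1	SULT1E1	protein-coding
NOTCH2	NOTCH2	protein-coding
RAD51D	RAD51D	protein-coding
RNASEL	RNASEL	protein-coding
BRCA2	BRCA2	protein-coding
CHEK2	CHEK2	protein-coding
MSH2	MSH2	protein-coding
MSH6	MSH6	protein-coding
MLH1	MLH1	protein-coding
PMS2	PMS2	protein-coding
ATM	ATM	protein-coding
HOXB13	HOXB13	protein-coding
AR	AR	protein-coding
BRIP1	BRIP1	protein-coding
RAD51	RAD51	protein-coding
RAD50	RAD50	protein-coding
MRE11	MRE11	protein-coding
NBN	NBN	protein-coding
XRCC1	XRCC1	protein-coding
FANCN	PALB2	protein-coding
ARIP4	RAD54L2	protein-coding
MMS2	UBE2V2	protein-coding
DJBP	EFCAB6	protein-coding
RIP140	NRIP1	protein-coding
SMRT	NCOR2	protein-coding
PCA3	PCA3	phenotype-only
PCAP	PCAP	phenotype-only
HPC6	HPC6	phenotype-only
PCAT4	PCAT4	non-coding RNA
PCAT5	PCAT5	non-coding RNA
PCAT6	PCAT6	non-coding RNA
PTENP1	PTENP1	pseudogene
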