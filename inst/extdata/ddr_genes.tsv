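symbol	alias
PALB2	FANCN
APTX	
BLM	
BRCA1	
CTBP1	
DDB2	
FANCA	
FANCL	
MBD5	
MSH3	
NEIL3	
RAD51D	
RAD54L2	ARIP4
SP1	
TP53BP1	
UBE2D3	
UBE2V2	MMS2
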