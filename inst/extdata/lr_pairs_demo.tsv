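ligand	receptor
CD274	PDCD1
PDCD1LG2	PDCD1
CD80	CTLA4
CD86	CTLA4
HLA-E	KLRK1
NECTIN1	CADM3
FGF1	FGFR4
CD44	FGFR2
SELL	CD34
SELP	CD34
NPPC	NPR1
NPPC	NPR2
TGFB1	TGFBR1
IL6	IL6R
CXCL12	CXCR4
CCL2	CCR2
VEGFA	KDR
EGF	EGFR
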