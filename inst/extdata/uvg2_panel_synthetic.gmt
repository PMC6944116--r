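UVG2_PANEL	synthetic 43-gene UV-G2 checkpoint pathway panel	ATR	CHEK1	TIMELESS	TIPIN	CDK1	CCND1	CDKN1A	CDKN2A	BTG2	MASTL	ENSA	ARPP19	PPP2R2A	PPP2R1A	STAT3	JUN	SMARCA4	GDF15	LZTS1	PHLDA3	SCRIB	CTNNA1	ACTA2	FBXO32	PCLAF	XPC	DDB1	DDB2	BRCA1	XRCC6	RAD51	RAD18	PARP1	FEN1	LIG1	NONO	FAM129A	VCP	PIAS4	SDHA	GADD45A	TP53I3	POLH
UVG2_CHECKPOINT	subset=checkpoint	ATR	CHEK1	TIMELESS	TIPIN	CDK1	CCND1	CDKN1A	CDKN2A	BTG2	MASTL	ENSA	ARPP19	PPP2R2A	PPP2R1A	STAT3	JUN	SMARCA4	GDF15	LZTS1	PHLDA3	SCRIB	CTNNA1	ACTA2	FBXO32	PCLAF
UVG2_REPAIR	subset=repair	XPC	DDB1	DDB2	BRCA1	XRCC6	RAD51	RAD18	PARP1	FEN1	LIG1	NONO	FAM129A	VCP	PIAS4	SDHA	GADD45A	TP53I3	POLH
UVG2_MASTL	subset=mastl	MASTL	ENSA	ARPP19	PPP2R2A	PPP2R1A
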