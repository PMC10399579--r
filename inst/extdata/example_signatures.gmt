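immune	example	PTPRC	CD3E	CD19	ITGAM	NKG7	CD14	FCGR3A	LCP1
non_immune	example	EPCAM	KRT18	KRT19	COL1A1	COL1A2	PECAM1	VWF	ALB
T	example	CD3D	CD3E	CD3G	CD2	TRAC	TRBC2	CD28	LCK
B	example	CD79A	CD79B	MS4A1	CD19	IGHM	BANK1	PAX5	BLNK
monocyte	example	LYZ	CD14	VCAN	FCN1	S100A8	S100A9	CSF1R	CD36
macrophage	example	CD68	CD163	MRC1	MSR1	MARCO	APOE	C1QA	C1QB
DC	example	FCER1A	CD1C	CLEC9A	LILRA4	ITGAX	BATF3	IRF8	FLT3
NK	example	NKG7	GNLY	KLRD1	NCAM1	KLRF1	NCR1	PRF1	EOMES
ILC	example	IL7R	KIT	RORC	GATA3	AHR	TNFRSF25	KLRB1	IL23R
mast	example	TPSAB1	TPSB2	CPA3	MS4A2	HDC	CMA1	GATA2	SLC18A2
neutrophil	example	FCGR3B	CSF3R	CXCR2	FUT4	MPO	ELANE	DEFA3	CEACAM8
CD4_T	example	CD4	IL7R	CD40LG	MAL	TSHZ2
CD8_T	example	CD8A	CD8B	GZMK	GZMH	LINC02446
naive_B	example	TCL1A	IGHD	FCER2	IL4R	CD72
memory_B	example	CD27	IGHG1	TNFRSF13B	AIM2	COCH
plasma	example	MZB1	XBP1	JCHAIN	PRDM1	SDC1
NK_bright	example	XCL1	XCL2	SELL	GZMK	CD44
NK_dim	example	FGFBP2	GZMB	CX3CR1	SPON2	HAVCR2
pDC	example	LILRA4	IRF7	TCF4	CLEC4C	IL3RA
cDC	example	CD1C	FCER1A	CLEC10A	BATF3	CLEC9A
classical_monocyte	example	CD14	VCAN	S100A12	FCN1	SELL
non_classical_monocyte	example	MS4A7	CDKN1C	CX3CR1	TCF7L2	LYPD2
M1_macrophage	example	IL1B	TNF	CXCL9	CXCL10	NOS2
M2_macrophage	example	CD163	MRC1	CCL22	TGM2	STAB1
ILC1	example	TBX21	IFNG	IL12RB2	CCL5	IKZF3
ILC2	example	PTGDR2	IL1RL1	HPGDS	IL17RB	GATA3
ILC3	example	RORC	IL23R	KIT	NCR2	LTA
CD4_naive	example	CCR7	SELL	TCF7	LEF1	NOSIP
CD4_central_memory	example	GPR183	ANXA1	CD69	LTB	AQP3
CD4_effector_memory	example	GZMA	CCL5	KLRB1	ITGB1	IL32
Treg	example	FOXP3	IL2RA	CTLA4	IKZF2	TNFRSF18
Tfh	example	CXCR5	ICOS	PDCD1	BCL6	TOX2
Th1	example	TBX21	CXCR3	IFNG	IL12RB2	STAT4
Th2	example	GATA3	CCR4	IL4	IL5	PTGDR2
Th17	example	RORC	CCR6	IL17A	IL17F	IL23R
CD8_naive	example	CCR7	SELL	TCF7	LEF1	S100B
CD8_central_memory	example	GZMK	IL7R	CD27	GPR183	NELL2
CD8_effector_memory	example	GZMH	CCL5	KLRG1	ITGB1	TRGC2
CD8_cytotoxic	example	GZMB	PRF1	GNLY	NKG7	KLRD1
CD8_exhausted	example	PDCD1	HAVCR2	LAG3	TIGIT	TOX
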