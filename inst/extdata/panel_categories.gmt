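cytotoxicity	granzyme/perforin mediated killing	PRF1	GZMA	GZMB	GZMH	GNLY	CTSW	KLRB1	KLRD1	KLRK1	NKG7	CD8A	CD8B
b_cell_functions	B-cell receptor signaling and maturation	BLK	CD19	FCRL2	MS4A1	TNFRSF17	TCL1A	SPIB	PNOC	FAM30A
t_cell_functions	T-cell activation and co-stimulation	CD3D	CD3E	CD3G	CD6	SH2D1A	TRAT1	CD2	TBX21	FOXP3	LAG3	CD244	EOMES	PTGER4
innate_immunity	NK, neutrophil, mast cell and dendritic programs	XCL1	XCL2	NCR1	KIR2DL3	KIR3DL1	KIR3DL2	IL21R	FPR1	SIGLEC5	CSF3R	FCAR	FCGR3B	CEACAM3	S100A12	MS4A2	TPSAB1	CPA3	HDC	CCL13	CD209	HSD11B1
myeloid_compartment	macrophage and monocyte markers	CD68	CD84	CD163	MS4A4A	PTPRC
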