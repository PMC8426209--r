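# Marker-gene signatures for 14 immune cell populations, after the
# published Danaher et al. pan-cancer signature resource. A population's
# score is the arithmetic mean of its markers' log2 normalized expression.
# Edit or replace freely; the file is data, not code.
#
# Note on CD56dim NK cells: the killer-cell immunoglobulin-like receptor
# marker is encoded here as the two full symbols KIR3DL1 and KIR3DL2.
B_cells: [BLK, CD19, FCRL2, MS4A1, TNFRSF17, TCL1A, SPIB, PNOC, FAM30A]
CD45: [PTPRC]
CD56dim_NK_cells: [KIR2DL3, KIR3DL1, KIR3DL2, IL21R]
CD8_T_cells: [CD8A, CD8B]
Cytotoxic_cells: [PRF1, GZMA, GZMB, GZMH, GNLY, CTSW, KLRB1, KLRD1, KLRK1, NKG7]
DC: [CCL13, CD209, HSD11B1]
Exhausted_CD8: [LAG3, CD244, EOMES, PTGER4]
Macrophages: [CD68, CD84, CD163, MS4A4A]
Mast_cells: [MS4A2, TPSAB1, CPA3, HDC]
Neutrophils: [FPR1, SIGLEC5, CSF3R, FCAR, FCGR3B, CEACAM3, S100A12]
NK_cells: [XCL1, XCL2, NCR1]
T_cells: [CD3D, CD3E, CD3G, CD6, SH2D1A, TRAT1, CD2]
Th1_cells: [TBX21]
Treg: [FOXP3]
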