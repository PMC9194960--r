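CD8_T_cells	synthetic stand-in marker set	CD8A	CD8B	GZMK	EOMES	CD3D	CD3E
Cytotoxic_lymphocytes	synthetic stand-in marker set	GZMA	GZMB	PRF1	KLRD1	NKG7	GNLY
B_lineage	synthetic stand-in marker set	CD19	MS4A1	CD79A	CD79B	IGKC	BANK1
Myeloid_dendritic_cells	synthetic stand-in marker set	CD1C	FCER1A	CLEC10A	ITGAX	HLA-DQA1	CLEC9A
T_cells	synthetic stand-in marker set	CD2	CD3G	CD5	TRAC	TRBC1	LCK
NK_cells	synthetic stand-in marker set	NCR1	KIR2DL3	KLRC1	XCL1	XCL2	NCAM1
Monocytic_lineage	synthetic stand-in marker set	CD14	CD68	CSF1R	FCGR1A	LYZ	ITGAM
Neutrophils	synthetic stand-in marker set	FCGR3B	CEACAM8	ELANE	MPO	CSF3R	S100A8
Endothelial_cells	synthetic stand-in marker set	PECAM1	VWF	CDH5	CLDN5	TEK	KDR
Fibroblasts	synthetic stand-in marker set	COL1A1	COL3A1	DCN	LUM	PDGFRB	FAP
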