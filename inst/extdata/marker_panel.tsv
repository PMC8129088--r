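gene_id	cell_type
Lcn5	principal
Lcn8	principal
Rnase10	principal
Defb42	principal
Acta2	myoid_fibroblast
Myh11	myoid_fibroblast
Col1a1	myoid_fibroblast
Atp6v1b1	clear_narrow
Atp6v0d2	clear_narrow
Foxi1	clear_narrow
Cd74	macrophage_monocyte
C1qa	macrophage_monocyte
C1qb	macrophage_monocyte
Krt5	basal
Krt14	basal
Trp63	basal
Cd3e	halo_T
Cd3g	halo_T
Ptprc	halo_T
Pecam1	endothelial
Flt1	endothelial
Vwf	endothelial
Prm1	sperm
Prm2	sperm
Smcp	sperm
Tnp2	sperm
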