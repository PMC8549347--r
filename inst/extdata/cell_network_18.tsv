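# 18-node immune-lineage cell-type network (synthetic stand-in built from
# standard hematopoietic lineage relationships: myeloid and lymphoid
# sub-graphs joined at antigen-presenting bridges)
B	B_Plasma
B	T_CD4
T_CD4	T_CD8
T_CD4	T_Reg
T_CD4	NKT
T_CD8	T_gd
T_CD8	NKT
NK	NKT
NK	ILC
NK	T_CD8
ILC	T_gd
Monocyte_Classical	Monocyte_NonClassical
Monocyte_Classical	Macrophage
Macrophage	Macrophage_Alveolar
Monocyte_NonClassical	Macrophage_Alveolar
cDC1	cDC2
cDC2	DC_Mature
cDC1	DC_Mature
pDC	cDC1
pDC	B
Monocyte_Classical	cDC2
Macrophage	Mast
cDC2	T_CD4
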