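ligand_gene	receptor_gene
COL1A1	CD44
COL1A1	ITGB1
COL1A2	CD44
COL1A2	ITGB1
COL6A3	ITGB1
THBS1	CD47
THBS1	SDC4
THBS2	CD47
TNC	SDC4
TNC	ITGA6
LAMA4	ITGA6
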