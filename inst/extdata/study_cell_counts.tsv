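# gliaProfiler study_cell_counts v1
region	genotype	n_cells
CSC	WT	310
CSC	MJD	389
DCN	WT	349
DCN	MJD	445
PN	WT	152
PN	MJD	180
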