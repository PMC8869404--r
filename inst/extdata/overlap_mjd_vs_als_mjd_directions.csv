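# gliaProfiler gene_set v1: MJD-model microglia directions for the 27 genes shared with the ALS (SOD1-G93A) microglial DEG set
gene,direction
Lamc1,up
Hipk3,up
Lrrc58,up
Bmpr2,up
Nav1,up
St8sia4,up
Cpd,up
Fmnl2,up
Atp6v0a1,up
Klhl24,up
Cnot1,up
Tmem106b,up
Xpr1,up
Rnh1,up
Bend6,down
Ups11,down
Tbkbp1,down
Ncam1,up
Arhgef15,up
Abcb1a,up
Alpl,up
Foxf2,up
Caskin2,up
Fbxl12,up
Gpld1,up
Csad,up
Plin2,down
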