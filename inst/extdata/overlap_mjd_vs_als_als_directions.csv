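# gliaProfiler gene_set v1: ALS (SOD1-G93A) microglia directions for the 27 genes shared with the MJD-model DEG set
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
Ncam1,down
Arhgef15,down
Abcb1a,down
Alpl,down
Foxf2,down
Caskin2,down
Fbxl12,down
Gpld1,down
Csad,down
Plin2,up
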