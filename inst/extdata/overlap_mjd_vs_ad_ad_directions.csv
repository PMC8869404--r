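# gliaProfiler gene_set v1: AD (App NL-G-F) microglia directions for the 31 genes shared with the MJD-model DEG set
gene,direction
Cux2,down
Ncam1,down
Arhgef12,down
Mkl2,down
Arhgef15,down
Abcb1a,down
Tyro3,down
Alpl,down
Foxf2,down
Sox8,down
Ahnak,down
Caskin2,down
Scd2,down
Atp2b4,down
Sh2d5,down
Gpld1,down
Syt3,down
Fbxw4,up
Plin2,up
Gm6548,up
Rnf144b,up
Epsti1,up
St8sia4,up
Cpd,up
Fos,up
Junb,up
Acsl4,up
Klhl24,up
Bend6,down
Phlpp1,down
Rbfox1,down
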