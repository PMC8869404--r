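# gliaProfiler gene_set v1: MJD-model microglia directions for the 31 genes shared with the AD (App NL-G-F) microglial DEG set
gene,direction
Cux2,up
Ncam1,up
Arhgef12,up
Mkl2,up
Arhgef15,up
Abcb1a,up
Tyro3,up
Alpl,up
Foxf2,up
Sox8,up
Ahnak,up
Caskin2,up
Scd2,up
Atp2b4,up
Sh2d5,up
Gpld1,up
Syt3,up
Fbxw4,down
Plin2,down
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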