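symbol,subset
CD3D,CD4_T
CD3E,CD8_T
CD4,CD4_T
CD8A,CD8_T
CD19,B
FCGR3A,NK
NCAM1,NK
CD14,monocyte
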