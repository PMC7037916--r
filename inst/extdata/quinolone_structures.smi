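OC(=O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O CIP
COC1=C2C(=CC(=C1N3C[C@@H]4CCCN[C@@H]4C3)F)C(=O)C(=CN2C5CC5)C(=O)O MOX
CCn1cc(C(=O)O)c(=O)c2cc(F)c(N3CCNCC3)cc21 NOR
CC1COc2c(N3CCN(C)CC3)c(F)cc3c(=O)c(C(=O)O)cn1c23 OFL
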