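variety,stem_elongation,heading_begins,milky_waxy,full_ripening,wsi_m
SC,0.21,0.31,0.27,0.21,0.25
MZ,0.16,0.19,0.23,0.17,0.19
SL,0.18,0.22,0.23,0.19,0.20
MixD1,0.14,0.20,0.21,0.16,0.18
MixD2,0.18,0.24,0.24,0.19,0.21
MixD3,0.15,0.19,0.17,0.14,0.16
MixD4,0.14,0.17,0.18,0.13,0.15
PG,0.23,0.31,0.28,0.23,0.26
SV,0.24,0.32,0.33,0.26,0.29
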