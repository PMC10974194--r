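variety,stem_elongation,heading_begins,milky_waxy,full_ripening,wsi_m
RS,0.18,0.23,0.23,0.17,0.20
RM,0.17,0.25,0.21,0.18,0.20
GR,0.19,0.22,0.25,0.17,0.21
MixC1,0.12,0.18,0.17,0.13,0.15
MixC2,0.13,0.19,0.18,0.14,0.16
MixC3,0.12,0.17,0.16,0.15,0.15
MixC4,0.16,0.21,0.19,0.17,0.18
AX,0.18,0.21,0.30,0.19,0.22
AL,0.23,0.32,0.27,0.21,0.26
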