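variety,wci_m,wci_pm
RS,0.78,0.04
RM,0.80,0.04
GR,0.93,0.05
MixC1,0.65,0.03
MixC2,0.63,0.04
MixC3,0.64,0.04
MixC4,0.75,0.04
AX,0.83,0.05
AL,0.85,0.04
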