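variety,wci_m,wci_pm
SC,0.93,0.05
MZ,0.78,0.04
SL,0.91,0.04
MixD1,0.70,0.03
MixD2,0.71,0.03
MixD3,0.63,0.04
MixD4,0.61,0.04
PG,0.83,0.04
SV,0.92,0.05
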