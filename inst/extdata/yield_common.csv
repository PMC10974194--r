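variety,yield_t_ha,yield_pm,culms_m2,culms_pm,spikes_m2,spikes_pm,biomass_t_ha,biomass_pm
RS,2.1,0.2,380,43,364,36,6.5,0.8
RM,1.8,0.1,414,34,394,35,6.2,0.1
GR,2.2,0.2,377,46,352,51,7.7,0.5
MixC1,1.5,0.1,275,22,260,20,6.1,0.2
MixC2,1.5,0.2,298,41,275,46,6.2,0.5
MixC3,1.6,0.3,367,41,341,46,5.6,0.5
MixC4,2.1,0.1,360,34,367,46,6.4,0.1
AX,2.8,0.2,380,55,378,46,6.8,0.6
AL,3.0,0.3,492,23,485,46,6.8,0.5
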