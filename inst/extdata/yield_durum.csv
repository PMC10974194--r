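variety,yield_t_ha,yield_pm,culms_m2,culms_pm,spikes_m2,spikes_pm,biomass_t_ha,biomass_pm
SC,2.6,0.2,302,15,273,8,10.0,1.0
MZ,1.8,0.2,322,32,296,24,6.6,0.6
SL,2.0,0.2,258,25,231,11,7.7,0.6
MixD1,1.9,0.3,355,16,327,11,7.8,0.9
MixD2,2.1,0.4,388,39,340,40,8.6,0.8
MixD3,1.7,0.3,245,30,199,54,7.5,0.5
MixD4,1.7,0.3,324,40,314,33,7.2,1.4
PG,2.4,0.2,221,29,215,31,5.7,0.6
SV,3.5,0.3,272,10,264,3,7.6,0.9
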