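factor,contribution_pct
TempSeasonality,40.6
Prec10,15.7
VegType,14.3
SoilType,9.2
Smean4_10,9.1
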