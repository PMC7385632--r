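category,n_factors
climate,59
soil,8
topography,3
vegetation,1
comprehensive-meteorological,3
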