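trait,type,weight
body_mass,quantitative,1
relative_brain_mass,quantitative,1
longevity,quantitative,1
litter_size,quantitative,1
generation_length,quantitative,1
dispersal_distance,quantitative,1
log_range_size,quantitative,1
habitat_breadth,ordinal,1
trophic_level,categorical,1
foraging_stratum,categorical,1
activity_cycle,categorical,1
hibernation,binary,1
fossoriality,binary,1
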