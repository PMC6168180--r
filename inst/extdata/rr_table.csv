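food,outcome,rr_per_unit,unit_size,ref_age,age_attenuation,pathway
fruits,chd,0.91,100,60,0.25,direct
fruits,stroke,0.82,100,60,0.25,direct
vegetables,chd,0.88,100,60,0.25,direct
vegetables,stroke,0.87,100,60,0.25,direct
nuts,chd,0.88,28.35,60,0.25,direct
nuts,diabetes,0.96,28.35,60,0.25,direct
whole_grains,chd,0.9,50,60,0.25,direct
whole_grains,stroke,0.95,50,60,0.25,direct
whole_grains,diabetes,0.88,50,60,0.25,direct
fish,chd,0.88,100,60,0.25,direct
plant_oils,chd,0.9,11,60,0.25,direct
ssb,chd,1.08,236,60,0.25,direct
ssb,stroke,1.02,236,60,0.25,direct
ssb,diabetes,1.13,236,60,0.25,direct
processed_meat,chd,1.24,50,60,0.25,direct
processed_meat,stroke,1.11,50,60,0.25,direct
processed_meat,diabetes,1.27,50,60,0.25,direct
red_meat,diabetes,1.1,100,60,0.25,direct
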