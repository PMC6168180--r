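component,delta_per_100g
fruits,-10
vegetables,-8
whole_grains,2.5
nuts,-1.2
plant_oils,1
processed_meat,5
red_meat,6
ssb,30
sodium,0.25
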