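food,spend_adult,spend_child
fruits,107.7939,73.2242
vegetables,137.1922,93.1944
nuts,12,8
whole_grains,25,20
fish,45,25
plant_oils,18,12
ssb,164.4374,129.1283
junk_food,164.4374,129.1283
processed_meat,82.2187,64.5642
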