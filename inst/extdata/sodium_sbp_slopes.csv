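race_group,hypertensive,slope,age_slope_per_decade,ref_age
nonblack,no,1,0.1,50
nonblack,yes,2.3,0.1,50
black,no,1.5,0.1,50
black,yes,3,0.1,50
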