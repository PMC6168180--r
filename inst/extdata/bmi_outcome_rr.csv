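outcome,rr_per_unit
chd,1.05
stroke,1.035
diabetes,1.15
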