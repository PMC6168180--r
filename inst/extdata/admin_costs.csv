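scenario,startup_millions,annual_millions
fv_incentive,108.4,3.52
fv_ssb_restriction,117,6.79
snap_plus,117,6.75
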