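age_group,bmi_group,slope
35-64,lt25,0.1
65-80,lt25,0.06
35-64,25-30,0.13
65-80,25-30,0.08
35-64,ge30,0.16
65-80,ge30,0.1
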