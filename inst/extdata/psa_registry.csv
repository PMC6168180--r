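parameter,family,arg1,arg2,lower,upper
effect_multiplier,normal,1,0.15,0.25,2
rr_log_multiplier,normal,1,0.15,0.25,2
risk_calibration,lognormal,0,0.1,0.5,2
admin_cost_multiplier,gamma,25,25,0.4,2.5
state_cost_multiplier,gamma,25,25,0.4,2.5
food_spend_multiplier,gamma,100,100,0.6,1.6
utility_decrement_multiplier,gamma,25,25,0.4,2.5
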