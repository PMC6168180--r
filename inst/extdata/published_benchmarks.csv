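scenario,horizon,cvd_events,diabetes,cvd_deaths,qalys,hc_savings_b,admin_m,subsidy_adults_b,subsidy_all_b
fv_incentive,5,38782,-361,2926,18928,1.21,125,5.04,11.54
fv_incentive,10,71616,56,5948,59259,2.15,144,8.6,19.65
fv_incentive,20,121788,-203,11713,155792,3.48,167,12.99,29.66
fv_incentive,lifetime,303911,-1077,41394,649376,6.77,212,21.81,49.89
fv_ssb_restriction,5,93933,30443,9628,45864,4.33,149,5.04,11.54
fv_ssb_restriction,10,181502,65499,19517,155646,9,185,8.6,19.66
fv_ssb_restriction,20,333591,116993,40420,457184,17.68,230,13,29.69
fv_ssb_restriction,lifetime,797888,171357,130938,2106832,39.16,317,21.88,50.04
snap_plus,5,116875,26138,11961,56056,5.28,149,-1.36,-4.93
snap_plus,10,222355,56924,24545,191318,10.56,185,-2.54,-8.96
snap_plus,20,398645,99657,48088,551824,19.69,230,-4.4,-15.04
snap_plus,lifetime,939965,146590,155807,2465008,41.93,316,-6.04,-21.51
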