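scenario,food,instrument,price_response,snap_dollar_share,snap_venue_share,spend_shift,snap_retail_share
fv_incentive,fruits,incentive,0.320987654320988,0.9,0.9,0.1,NA
fv_incentive,vegetables,incentive,0.260631001371742,0.9,0.9,0.1,NA
fv_ssb_restriction,fruits,incentive,0.320987654320988,0.9,0.9,0.1,NA
fv_ssb_restriction,vegetables,incentive,0.260631001371742,0.9,0.9,0.1,NA
fv_ssb_restriction,ssb,restriction,NA,NA,NA,0.5,0.664
snap_plus,fruits,incentive,0.320987654320988,0.9,0.9,0.1,NA
snap_plus,vegetables,incentive,0.293072498809393,0.9,0.9,0.1,NA
snap_plus,nuts,incentive,0.431844739114972,0.9,0.9,0.1,NA
snap_plus,whole_grains,incentive,0.335534041902281,0.9,0.9,0.1,NA
snap_plus,fish,incentive,0.259698749450637,0.9,0.9,0.1,NA
snap_plus,plant_oils,incentive,0.278749734087425,0.9,0.9,0.1,NA
snap_plus,ssb,disincentive,-0.172296110746639,0.9,0.9,0.1,NA
snap_plus,junk_food,disincentive,-0.237218560805305,0.9,0.9,0.1,NA
snap_plus,processed_meat,disincentive,-0.219996376530269,0.9,0.9,0.1,NA
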