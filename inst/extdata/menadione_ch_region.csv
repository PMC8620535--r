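exp_position,exp_intensity,calc_position,calc_intensity,difference,fundamental,class,assignment
NA,NA,3376,11.0,NA,FALSE,first_overtone,"2(δring, νC=O)"
3310,40.7,3360,35.1,-50,FALSE,binary_combination,"(δring, νC=O) + (δring, νC=O); 2(δring, νC=O)"
3272,30.4,3331,10.2,-59,FALSE,binary_combination,"(δring, νC=O) + (δring, νC=O)"
3234,11.9,3285,3.5,-51,FALSE,first_overtone,"2(δring, νC=O)"
3183,16.7,3183,8.8,0,FALSE,binary_combination,"(δring, δCH) + (δring, δCH)"
3173,19.8,3167,22.9,6,FALSE,first_overtone,"2(δring, δCH)"
3152,19.9,3141,15.9,11,FALSE,binary_combination,"δCH + (δring, νC=O)"
3126,27.7,3127,14.3,-1,FALSE,binary_combination,"δCH + (δring, νC=O)"
3095,54.1,3105,12.9,-10,FALSE,binary_combination,"δCH + (δring, δCH)"
3075,88.0,3063,100.0,12,FALSE,binary_combination,"νCH; δsymCH3 + (δring, νC=O)"
3070,100.0,3063,100.0,7,FALSE,binary_combination,"νCH; δsymCH3 + (δring, νC=O)"
3046,64.1,3037,60.2,9,TRUE,fundamental,"νCH"
3038,65.6,3037,60.2,1,TRUE,fundamental,"νCH"
3017,43.5,3003,21.6,14,TRUE,fundamental,"νCH"
3009,45.8,3003,21.6,6,TRUE,fundamental,"νCH"
2979,50.6,2984,49.1,-5,TRUE,fundamental,"νasCH3"
2958,64.5,2942,51.6,16,TRUE,fundamental,"νasCH3"
2920,79.5,2934,54.9,-14,TRUE,fundamental,"νsCH3"
2892,21.9,2897,8.7,-5,FALSE,binary_combination,"δring + (δring, δCH)"
2878,20.2,2886,7.9,-8,FALSE,binary_combination,"(δring, δCH) + (δring, δCH)"
2860,16.1,2861,10.9,-1,FALSE,first_overtone,"2δasymCH3"
2842,21.8,2832,12.4,10,FALSE,first_overtone,"2δasymCH3"
2813,9.3,2817,6.7,-4,FALSE,binary_combination,"δsymCH3 + δasymCH3"
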