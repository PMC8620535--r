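exp_position,calc_position,calc_intensity,difference,class,assignment
3998,3994,1.6,4,binary_combination,"(δring, ρCH3) + νasCH3"
3970,3981,1.5,-11,binary_combination,"δring + νCH"
3951,3956,1.5,-5,binary_combination,"ρCH3 + νsCH3"
3940,3933,0.9,7,binary_combination,"(δring, ρCH3) + νsCH3"
3868,3854,1.6,14,binary_combination,"(δring, ρCH3) + νCH"
3859,3834,2.5,25,binary_combination,"(δring, ρCH3) + νCH"
3802,3781,0.6,21,binary_combination,"δring + νCH"
3788,3781,0.6,7,binary_combination,"δring + νCH"
3748,3755,0.9,-7,binary_combination,"δring + νCH"
3718,3721,1.2,-3,binary_combination,"δring + νCH"
3687,3694,0.8,-7,binary_combination,"δring + νCH"
3663,3655,0.2,8,binary_combination,"δring + νasCH3"
3627,3635,0.2,-8,binary_combination,"δring + νasCH3"
3610,3620,0.4,-10,binary_combination,"(γring, ρCH3) + νasCH3"
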