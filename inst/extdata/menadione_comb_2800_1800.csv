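exp_position,calc_position,calc_intensity,difference,class,assignment
2781,2780,1.1,1,binary_combination,"δasymCH3 + (δring, δCH)"
2759,2750,1.9,9,binary_combination,"(δring, δCH) + δCH"
2747,2743,3.6,4,first_overtone,"2δsymCH3"
2727,2737,1.6,-10,binary_combination,"(δring, δCH) + δCH"
2711,2723,1.6,-12,binary_combination,"δsymCH3 + (δring, δCH)"
2702,2713,2.1,-11,binary_combination,"(δring, δCH) + δCH"
2680,2687,4.4,-7,binary_combination,"(δring, δCH) + (δring, δCH)"
2655,2661,3.4,-6,binary_combination,"(δring, ρCH3) + (δring, νC=O)"
2625,2652,5.5,-27,first_overtone,"2δring"
2600,2633,1.5,-33,binary_combination,"(δring, δCH) + (δring, δCH)"
2586,2616,2.4,-30,binary_combination,"(δring, δCH) + δring"
2564,2603,2.8,-39,binary_combination,"(δring, δCH) + (δring, δCH)"
2550,2580,3.4,-30,first_overtone,"2(δring, δCH)"
2536,2547,2.3,-11,binary_combination,"(δring, δCH) + δsymCH3"
2505,2506,1.6,-1,binary_combination,"(δring, δCH) + (δring, δCH)"
2489,2495,2.7,-6,binary_combination,"(δring, δCH) + (δring, δCH)"
2456,2462,1.2,-6,binary_combination,"ρCH3 + δasymCH3"
2443,2451,2.3,-8,binary_combination,"(δring, ρCH3) + δasymCH3"
2414,2432,2.2,-18,binary_combination,"(δring, δCH) + (δring, δCH)"
2396,2418,1.6,-22,binary_combination,"ρCH3 + δsymCH3"
2378,2381,2.1,-3,binary_combination,"(δring, δCH) + (δring, δCH)"
2371,2370,4.1,1,binary_combination,"(δring, δCH) + (δring, δCH)"
2330,2333,4.1,-3,first_overtone,"2(δring, δCH)"
2318,2323,2.9,-5,first_overtone,"2(δring, δCH); (δring, δCH) + (δring, δCH)"
2292,2298,1.3,-6,binary_combination,"δring (breath) + (δring, δCH)"
2275,2282,2.1,-7,binary_combination,"δring + (δring, δCH)"
2270,2275,2.1,-5,binary_combination,"(δring, δCH) + (δring, δCH)"
2250,2255,2.2,-5,binary_combination,"(δring, δCH) + (δring, δCH)"
2223,2217,1.8,6,first_overtone,"2(δring, δCH)"
2203,2204,2.8,-1,binary_combination,"δring + (δring, δCH)"
2188,2176,2.3,12,binary_combination,"δring + (δring, δCH)"
2172,2163,1.8,9,binary_combination,"δring + (δring, νC=O)"
2143,2140,3.1,3,binary_combination,"(δring, ρCH3) + (δring, δCH)"
2111,2123,1.6,-12,binary_combination,"(δring, ρCH3) + (δring, δCH)"
2114,2110,1.2,4,binary_combination,"(δring, ρCH3) + (δring, δCH)"
2098,2089,2.3,9,binary_combination,"(δring, ρCH3) + (δring, δCH)"
2093,2080,1.5,13,first_overtone,"2ρCH3"
2074,2057,1.9,17,binary_combination,"δring + (δring, δCH)"
2058,2052,1.6,6,binary_combination,"δring + (δring, νC=O)"
2029,2030,1.4,-1,binary_combination,"(δring, ρCH3) + (δring, δCH)"
2008,2009,4.6,-1,binary_combination,"δring + (δring, δCH)"
2008,1997,9.0,11,first_overtone,"2γCH"
1981,1977,12.0,4,binary_combination,"γCH + γCH"
1954,1959,3.5,-5,first_overtone,"2γCH"
1946,1943,2.2,3,binary_combination,"δring + (δring, δCH)"
1903,1913,5.0,-10,binary_combination,"γCH + γCH"
1903,1905,6.8,-2,binary_combination,"γCH + γCH"
1877,1892,6.5,-15,binary_combination,"γCH + γCH"
1877,1884,9.1,-7,binary_combination,"γCH + γCH"
1840,1860,1.9,-20,binary_combination,"δring + (δring, δCH)"
1825,1824,5.6,1,first_overtone,"2γCH"
1810,1817,7.8,-7,binary_combination,"γCH + γCH"
1810,1807,9.0,3,binary_combination,"δring + (δring, δCH)"
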