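exp_position,exp_intensity_label,gatti_position,gatti_intensity,tzvp_position,tzvp_intensity,diff_gatti,diff_tzvp,assignment
1664,vs,1692,82.5,1665,100.0,-28,-1,"δring, νC=O"
1652,vs,1679,100.0,NA,NA,-27,NA,"δring, νC=O"
1623,m,1645,33.3,1632,26.5,-22,-9,"δring (νCC), νC=O"
1590,s,1609,49.1,1601,89.7,-19,-11,"δring, δCH"
1461,w,1492,1.8,1484,11.8,-31,-23,"δring, δCH, δasCH3"
1440,w,1472,7.0,1471,5.9,-32,-31,"δasCH3"
1425,w,1459,5.3,1413,8.8,-34,12,"δasCH3"
1380,m,1409,8.8,1372,17.6,-29,8,"δsCH3"
1353,m,1368,12.3,1351,8.8,-15,2,"δring, δCH"
1329,m,1356,3.5,NA,NA,-27,NA,"δring, δCH"
1299,s,1310,66.7,1314,41.2,-11,-15,"δring, δCH"
1264,m,1274,50.9,1281,44.1,-10,-17,"δring, δCH"
1238,w,1241,5.3,1251,4.4,-3,-13,"δring, δCH"
1169,w,1187,1.8,1190,4.4,-18,-21,"δring, δCH"
1156,m,1177,1.8,1177,7.4,-21,-21,"δring, δCH"
1107,vw,1126,14.0,1130,2.9,-19,-23,"δring, δCH"
1030,vw,1055,3.5,1065,1.5,-25,-35,"γCH, ρCH3"
1019,w,1029,3.5,1040,7.4,-10,-21,"γCH, ρCH3"
940,w,950,5.3,961,5.9,-10,-21,"δring"
900,w,930,10.5,935,5.9,-30,-35,"γring, γCH, ρCH3"
883,w,919,7.0,NA,NA,-36,NA,"γring, γCH, ρCH3"
791,w,807,12.3,809,8.8,-16,-18,"γring, γCH"
777,s,798,12.3,795,5.9,-21,-18,"γring, γCH"
720,w,722,3.5,727,1.5,-2,-7,"δring"
690,m,703,10.5,694,14.7,-13,-4,"γring"
664,m,685,5.3,676,8.8,-21,-12,"γring"
650,vw,657,1.8,665,2.9,-7,-15,"δring"
642,vw,651,1.8,654,1.5,-9,-12,"δring"
514,w,524,3.5,523,1.5,-10,-9,"δring"
459,w,464,3.5,468,1.5,-5,-9,"δring"
405,w,412,5.3,414,4.4,-7,-9,"δring"
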