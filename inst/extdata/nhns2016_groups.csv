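sex,age_lower,age_upper,n,height_mean,height_sd,weight_mean,weight_sd,bmi_mean,bmi_sd,food_beverage_weight_mean,food_beverage_weight_sd,beverage_fluid_ml,ei_kj_mean,ei_kj_sd,calibrated_ei_kj_mean,calibrated_ei_kj_sd,protein_g_mean,protein_g_sd,fat_g_mean,fat_g_sd,carbohydrate_g_mean,carbohydrate_g_sd,food_quotient,pbmr_kj,pal
male,15,19,559,170.1,5.2,60.4,9.2,20.9,3.0,2111,645,1648,10148,2678,11061,2916,85.7,26.4,76.6,27.1,334.6,99.4,0.89,6237,1.77
male,20,29,710,171.5,5.8,67.6,12.4,22.9,3.8,2029,741,1620,8842,2824,9638,3075,74.5,26.2,67.7,27.5,285.6,107.5,0.88,6496,1.48
male,30,39,1207,171.5,5.6,69.2,11.1,23.5,3.5,2094,689,1687,8754,2477,9541,2699,73.6,22.7,65.0,26.6,278.0,86.7,0.89,6439,1.48
male,40,49,1581,171.4,5.4,70.9,11.4,24.1,3.6,2192,719,1775,8877,2356,9676,2569,74.8,22.9,64.6,25.4,278.8,83.3,0.89,6380,1.52
male,50,59,1486,169.8,5.4,69.7,10.0,24.1,3.1,2291,697,1867,8976,2188,9784,2385,76.1,21.6,63.2,23.3,282.1,76.6,0.89,6147,1.59
male,60,69,2307,167.0,5.4,66.6,9.0,23.9,2.8,2397,691,1945,9037,2125,9850,2318,79.1,22.4,61.7,22.4,286.4,75.2,0.89,5801,1.70
male,70,NA,2696,162.1,5.8,61.6,9.0,23.4,2.9,2241,614,1802,8353,1941,9105,2117,74.4,20.9,54.7,20.8,277.7,70.4,0.90,5368,1.70
female,15,19,491,157.0,5.8,50.1,6.6,20.3,2.2,1644,508,1299,7420,2033,8087,2218,64.8,19.8,61.4,23.2,232.5,68.3,0.88,4874,1.66
female,20,29,779,158.2,5.5,53.2,8.8,20.9,3.3,1646,542,1312,6823,1895,7437,2067,60.5,18.0,55.0,21.3,215.2,67.2,0.88,4905,1.52
female,30,39,1350,158.1,5.1,53.6,8.4,21.5,3.2,1786,569,1443,7087,1866,7725,2033,62.1,18.5,56.0,21.5,224.6,64.6,0.88,4828,1.60
female,40,49,1819,157.9,5.3,55.5,9.8,22.3,3.8,1831,605,1494,7017,1828,7649,1992,60.7,18.6,55.1,21.2,221.4,63.7,0.88,4777,1.60
female,50,59,1777,156.7,4.9,55.2,8.7,22.5,3.4,1987,536,1620,7225,1669,7875,1820,65.2,18.0,55.9,20.9,230.2,58.9,0.88,4597,1.71
female,60,69,2641,153.4,4.8,53.9,7.8,22.9,3.2,2073,526,1680,7324,1615,7984,1761,67.8,18.1,54.3,19.2,238.5,58.6,0.89,4325,1.85
female,70,NA,3498,148.8,5.7,50.5,8.2,22.8,3.4,1954,559,1564,6957,1699,7583,1849,64.1,19.0,48.3,19.0,238.0,60.9,0.89,3975,1.91
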