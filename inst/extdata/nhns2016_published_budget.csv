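sex,age_lower,age_upper,n,wt,w_met,w_res,w_trans,w_pre
male,15,19,559,3291,355,124,76,2735
male,20,29,710,3151,309,108,80,2654
male,30,39,1207,3213,307,107,81,2718
male,40,49,1581,3243,311,109,81,2742
male,50,59,1486,3205,316,110,80,2699
male,60,69,2307,3104,318,111,78,2597
male,70,NA,2696,2790,295,103,75,2318
female,15,19,491,2641,258,90,66,2228
female,20,29,779,2594,237,83,68,2206
female,30,39,1350,2741,247,86,68,2339
female,40,49,1819,2739,245,86,69,2339
female,50,59,1777,2753,252,88,69,2345
female,60,69,2641,2707,256,90,67,2294
female,70,NA,3498,2482,244,86,64,2088
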