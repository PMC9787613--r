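# Published coefficient sets for the six trans-species leaf mass equations,
# fitted on the full national destructive-sampling compilation. Response is
# ln(dry leaf mass, kg); all predictors enter on the natural-log scale and
# mean annual temperature is translated by +30 degC before the log. Crown
# class supplies a variable intercept (cell means, five levels) for every
# equation except eq3, which has a single global intercept. estimate/se pairs
# as printed; terms absent from an equation are simply not listed.
equation,term,estimate,se
eq1,lnDBH,1.703,0.017
eq1,lnLL,0.413,0.010
eq1,lnLCR,0.755,0.028
eq1,lnSG,0.689,0.053
eq1,lnST,0.236,0.024
eq1,lnMAT30,2.049,0.114
eq1,lnMAP,-0.191,0.038
eq1,cc_open_grown,-9.947,0.334
eq1,cc_dominant,-9.789,0.044
eq1,cc_codominant,-9.932,0.041
eq1,cc_intermediate,-10.176,0.042
eq1,cc_overtopped,-10.346,0.042
eq2,lnDBH,1.708,0.017
eq2,lnLL,0.406,0.010
eq2,lnLCR,0.750,0.028
eq2,lnSGp,0.800,0.054
eq2,lnST,0.221,0.024
eq2,lnMAT30,1.701,0.118
eq2,lnMAP,-0.180,0.037
eq2,cc_open_grown,-8.632,0.360
eq2,cc_dominant,-8.456,0.043
eq2,cc_codominant,-8.601,0.041
eq2,cc_intermediate,-8.839,0.042
eq2,cc_overtopped,-9.009,0.042
eq3,lnDBH,1.825,0.018
eq3,(Intercept),-3.711,0.054
eq4,lnDBH,1.647,0.021
eq4,lnLCR,0.593,0.030
eq4,cc_open_grown,-2.490,0.066
eq4,cc_dominant,-2.567,0.053
eq4,cc_codominant,-2.678,0.049
eq4,cc_intermediate,-3.004,0.049
eq4,cc_overtopped,-3.089,0.050
eq5,lnDBH,1.679,0.021
eq5,lnLCR,0.775,0.033
eq5,lnMAT30,1.063,0.129
eq5,lnMAP,-0.009,0.044
eq5,cc_open_grown,-6.442,0.365
eq5,cc_dominant,-6.482,0.052
eq5,cc_codominant,-6.584,0.049
eq5,cc_intermediate,-6.874,0.049
eq5,cc_overtopped,-6.970,0.050
eq6,lnDBH,1.692,0.017
eq6,lnLL,0.346,0.009
eq6,lnLCR,0.748,0.028
eq6,lnST,0.254,0.024
eq6,lnMAT30,2.198,0.116
eq6,lnMAP,-0.156,0.039
eq6,cc_open_grown,-11.100,0.329
eq6,cc_dominant,-9.110,0.045
eq6,cc_codominant,-11.046,0.042
eq6,cc_intermediate,-11.301,0.043
eq6,cc_overtopped,-11.473,0.043
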