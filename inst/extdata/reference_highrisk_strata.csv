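row,probability,rr,n,forecast_case,forecast_control,fact_case,fact_control
46,0.005790,11.65,20,20,0,17,3
47,0.007317,14.72,0,0,0,0,0
48,0.007525,15.14,0,0,0,0,0
49,0.007570,15.23,2,2,0,2,0
50,0.007654,15.40,0,0,0,0,0
51,0.011637,23.41,0,0,0,0,0
52,0.011707,23.56,0,0,0,0,0
53,0.012039,24.22,26,26,0,22,4
54,0.012320,24.79,0,0,0,0,0
55,0.018619,37.46,8,8,0,8,0
56,0.019593,39.42,0,0,0,0,0
57,0.019711,39.66,0,0,0,0,0
58,0.031349,63.08,3,3,0,3,0
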