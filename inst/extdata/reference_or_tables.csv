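label,a,b,c,d,or_printed,ci_low_printed,ci_high_printed
family_history_any,201,432,127,438,1.60,1.24,2.08
relatives_1,149,432,111,438,1.36,1.03,1.80
relatives_2plus,52,432,16,438,3.30,1.85,5.86
under50_family_history,39,86,24,112,2.12,1.18,3.78
under50_relatives_1,32,86,23,112,1.81,0.99,3.32
under50_relatives_2plus,7,86,1,112,9.12,1.10,75.50
over50_family_history,162,346,103,326,1.48,1.11,1.98
over50_relatives_1,117,346,88,326,1.25,0.91,1.72
over50_relatives_2plus,45,346,15,326,2.83,1.55,5.17
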