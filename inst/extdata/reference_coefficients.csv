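term,estimate,std_error
sex,0.464,0.178
smoking_light,0.135,0.241
smoking_heavy,1.545,0.211
lung_disease_history,1.689,0.322
occupation_expose,0.470,0.172
relatives_1,0.436,0.158
relatives_2plus,0.957,0.318
(intercept),-0.867,0.102
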