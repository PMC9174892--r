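parameter,rest_mean,rest_sd,stress_mean,stress_sd,p_value
age_years,33,13,NA,NA,NA
height_cm,172,8,NA,NA,NA
weight_kg,68,8,NA,NA,NA
hr_bpm,66,9,108,13,<0.001
bp_systolic_mmhg,118,13,135,15,0.021
bp_diastolic_mmhg,68,9,63,8,0.251
lvedv_ml,153,28,139,35,0.004
lvesv_ml,65,17,36,13,<0.001
lvef_pct,58,5,74,5,<0.001
lvsv_ml,88,13,102,25,0.010
co_l_min,5.8,1.0,11.0,2.4,<0.001
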