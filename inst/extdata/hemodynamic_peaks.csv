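parameter,region,rest_mean,rest_sd,stress_mean,stress_sd,p_value
peak_v_avg,AAo,0.70,0.11,1.17,0.26,0.002
peak_v_avg,AoA,0.66,0.12,1.02,0.20,<0.001
peak_v_avg,DAo,0.87,0.16,1.32,0.25,0.002
peak_v_avg,TAo,0.74,0.11,1.17,0.22,<0.001
peak_v_max,AAo,1.24,0.11,1.98,0.21,0.002
peak_v_max,AoA,0.96,0.16,1.46,0.29,<0.001
peak_v_max,DAo,1.20,0.19,1.75,0.31,<0.001
peak_v_max,TAo,1.31,0.13,2.00,0.25,<0.001
peak_tke_total,AAo,1.47,0.50,4.09,1.48,<0.001
peak_tke_total,AoA,0.36,0.12,0.88,0.26,<0.001
peak_tke_total,DAo,1.16,0.42,3.41,1.54,<0.001
peak_tke_total,TAo,2.86,0.67,8.04,2.20,<0.001
peak_tke_max,AAo,171.4,33.7,316.7,73.4,<0.001
peak_tke_max,AoA,121.9,43.5,200.9,59.8,0.002
peak_tke_max,DAo,135.3,35.7,253.5,80.6,<0.001
peak_tke_max,TAo,176.3,32.6,334.2,69.0,<0.001
peak_tke_med,AAo,43.6,12.6,112.8,30.7,<0.001
peak_tke_med,AoA,38.1,16.5,82.8,25.8,0.002
peak_tke_med,DAo,34.5,10.9,91.4,34.1,<0.001
peak_tke_med,TAo,35.8,7.2,93.2,23.5,0.002
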