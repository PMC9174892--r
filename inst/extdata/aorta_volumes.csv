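region,rest_mean,rest_sd,stress_mean,stress_sd,p_value
AAo,35.4,9.3,35.7,9.7,0.538
AoA,11.3,3.0,11.3,2.9,0.880
DAo,37.3,8.2,38.0,7.9,0.400
TAo,84.3,16.8,85.6,17.5,0.150
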