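segment	covered	thickness	conductivity	specific_heat
head	0	NA	NA	NA
shoulder	1	0.0004	0.034	648
chest	1	0.0004	0.034	648
abdomen	1	0.0004	0.034	648
upper_arm	1	0.0004	0.034	648
lower_arm	0	NA	NA	NA
hand	0	NA	NA	NA
l_thigh	1	0.0009	0.031	375
r_thigh	1	0.0009	0.031	375
l_calf	0	NA	NA	NA
r_calf	0	NA	NA	NA
feet	0	NA	NA	NA
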