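segment	covered	thickness	conductivity	specific_heat
head	0	NA	NA	NA
shoulder	1	0.0055	0.062	161
chest	1	0.0055	0.062	161
abdomen	1	0.0055	0.062	161
upper_arm	1	0.0055	0.062	161
lower_arm	1	0.0055	0.062	161
hand	0	NA	NA	NA
l_thigh	1	0.0051	0.037	282
r_thigh	1	0.0051	0.037	282
l_calf	1	0.0051	0.037	282
r_calf	1	0.0051	0.037	282
feet	1	0.0051	0.037	282
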