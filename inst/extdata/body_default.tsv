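segment	area	d_core	d_eq	d_skin	k_eq	c_eq	Q0_core	Q0_eq	Q0_skin	Tset_core	Tset_eq	Tset_skin	Bb_core	Bb_eq	Bb_skin	SKINR	SKINV	SKINC	Metf	hc_shape
head	0.1344	0.060	0.025	0.002	0.1	2318.4	14.00	2.80	0.37	36.9	36.5	35.6	45.0	3.0	4.3	0.07	0.07	0.050	0.02	1.10
shoulder	0.1728	0.040	0.030	0.002	0.8	1678.6	2.00	1.50	0.30	36.9	36.0	34.5	3.0	4.0	2.0	0.10	0.10	0.050	0.08	0.90
chest	0.2064	0.060	0.035	0.002	0.1	1547.0	14.00	2.50	0.30	36.9	36.0	34.5	80.0	4.0	2.0	0.15	0.15	0.050	0.10	0.90
abdomen	0.2592	0.060	0.045	0.002	0.2	2219.7	18.50	3.30	0.49	36.9	36.0	34.5	100.0	5.0	2.3	0.20	0.20	0.050	0.18	0.90
upper_arm	0.1536	0.025	0.025	0.002	0.2	1764.0	0.50	0.639	0.15	36.9	36.0	34.2	0.5	2.5	1.0	0.06	0.06	0.050	0.08	1.20
lower_arm	0.1152	0.020	0.020	0.002	0.1	1861.2	0.30	0.45	0.12	36.9	36.0	34.0	0.4	1.6	0.9	0.06	0.06	0.100	0.04	1.30
hand	0.1152	0.008	0.008	0.002	0.1	1861.2	0.10	0.15	0.15	36.9	36.0	34.4	0.1	0.5	2.2	0.05	0.05	0.175	0.01	1.40
l_thigh	0.1776	0.030	0.035	0.002	0.05	1000.0	1.00	4.30	0.20	36.9	36.0	34.3	0.8	5.0	1.3	0.08	0.08	0.050	0.15	1.10
r_thigh	0.1776	0.030	0.035	0.002	0.05	1000.0	1.00	4.30	0.20	36.9	36.0	34.3	0.8	5.0	1.3	0.08	0.08	0.050	0.15	1.10
l_calf	0.1248	0.020	0.025	0.002	0.12	2354.4	0.50	2.35	0.15	36.9	36.0	34.0	0.4	2.5	0.9	0.06	0.06	0.100	0.09	1.25
r_calf	0.1248	0.020	0.025	0.002	0.12	2354.4	0.50	2.35	0.15	36.9	36.0	34.0	0.4	2.5	0.9	0.06	0.06	0.100	0.09	1.25
feet	0.1584	0.010	0.012	0.002	0.12	2354.4	0.20	0.30	0.20	36.9	36.0	34.5	0.2	1.0	1.9	0.03	0.03	0.175	0.01	1.30
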