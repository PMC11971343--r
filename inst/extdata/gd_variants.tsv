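variant	substitutions	net_charge	tm_K	tm_se_K	rel_csp_sum	rel_csp_sum_se	kd_uM	kd_se_uM
WT	-	9	321.8	0.1	1.0	0.1	17	6
4R4K	R42K,R47K,R74K,R94K	9	318.5	0.1	0.80	0.08	15	8
12K1	A34K,Q67K	11	313.4	0.1	1.7	0.2	2	1
12K1_DE	A34K,Q67K,D30N,E39Q	13	301.6	0.3	2.0	0.2	2.0	0.2
12K2	L70K,S90K	11	316.5	0.1	1.8	0.2	4.0	0.2
2E2K	E39K,E62K	13	313.1	0.1	1.8	0.2	1.3	0.2
2E2Q	E39Q,E62Q	11	313.3	0.1	1.4	0.1	1.7	0.4
H57K	H57K	10	315.6	0.1	1.0	0.1	18	5
H57Q	H57Q	9	312.2	0.2	1.1	0.1	17	2
8K1	K82Q,K52Q	7	323.3	0.1	0.63	0.06	26	6
8K2	K85Q,K73Q	7	326.4	0.1	0.34	0.03	191	54
8K3	K59Q,K69Q	7	325.9	0.1	0.39	0.04	131	38
6K1	K82Q,K52Q,K85Q,K73Q	5	327.8	0.1	0.11	0.01	NA	NA
6K2	K85Q,K73Q,K40Q,K97Q	5	325.7	0.1	0.13	0.01	NA	NA
73_34	K73A,A34K	9	322.2	0.1	0.54	0.05	36	18
73_66	K73S,S66K	9	322.1	0.1	0.88	0.08	17	4
73_70	K73L,L70K	9	324.3	0.1	1.0	0.1	10	2
74_34	R74A,A34R	9	317.3	0.1	0.63	0.06	64	17
74_67	R74Q,Q67R	9	318.9	0.1	0.99	0.09	24	6
74_70	R74L,L70R	9	322.6	0.1	1.2	0.1	5.7	0.3
82_78	K82T,T78K	9	321.7	0.1	1.3	0.1	10	4
85_90	K85S,S90K	9	320.0	0.1	1.0	0.1	10	6
94_90	R94S,S90R	9	317.3	0.1	1.4	0.1	4.6	0.6
2S1	K85S,S90K,K73A,A34K	9	319.2	0.1	0.57	0.05	34	8
2S2	R74L,L70R,K73S,S66K	9	321.1	0.1	1.0	0.1	13.8	0.8
2S3	K73Q,R74Q,Q37K,Q48R	9	326.6	0.1	1.1	0.1	18	3
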