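date	epoch	p_per_hac	gly_per_hac	phb_per_hac	phv_per_hac	pha_per_hac	p_per_pha	gly_per_pha
2013-05-29	high	0.92	0.74	0.51	0.06	0.57	0.67	0.67
2013-06-05	high	0.80	0.63	0.69	0.07	0.76	0.90	0.52
2013-06-12	high	1.01	0.58	0.84	0.13	0.97	0.73	0.60
2013-06-19	high	0.83	0.44	1.30	0.20	1.50	0.73	0.64
2013-06-26	low	0.82	0.34	0.94	0.17	1.11	0.82	NA
2013-07-03	low	0.99	0.39	0.96	0.20	1.16	0.84	0.53
2013-07-10	low	0.86	0.34	1.03	0.18	1.21	0.72	0.49
2013-07-16	low	0.93	0.37	1.01	0.21	1.22	0.75	0.51
2013-07-25	low	0.94	0.44	0.90	0.19	1.09	1.04	0.47
2013-08-14	low	0.81	0.38	0.81	0.19	1.00	0.76	0.65
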