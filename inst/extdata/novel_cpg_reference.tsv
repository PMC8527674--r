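cpg	trait	level	effect	se	p	p_het	p_fdr
cg02871985	bmi	chinese	-40.31	15.26	8.24e-03	2.39e-01	NA
cg07421368	bmi	chinese	43.06	8.58	5.16e-07	9.75e-01	NA
cg07421368	wc	chinese	112.10	21.27	1.36e-07	3.55e-01	NA
cg15103625	bmi	chinese	35.49	8.14	1.29e-05	4.48e-01	NA
cg15103625	wc	chinese	92.50	20.69	7.83e-06	5.20e-01	NA
cg08010984	bmi	chinese	-27.24	6.41	2.14e-05	9.01e-01	NA
cg16309866	bmi	chinese	-38.87	7.96	1.05e-06	4.06e-01	NA
cg19120513	bmi	chinese	-31.09	9.00	5.53e-04	6.78e-01	NA
cg02871985	bmi	trans	-47.88	10.46	4.75e-06	5.83e-01	0.043
cg07421368	bmi	trans	39.68	8.43	2.55e-06	1.37e-01	0.035
cg07421368	wc	trans	105.05	20.86	4.77e-07	2.57e-01	0.048
cg15103625	bmi	trans	32.85	6.75	1.12e-06	6.99e-01	0.025
cg15103625	wc	trans	88.37	16.49	8.32e-08	7.54e-01	0.026
cg08010984	bmi	trans	-24.98	5.43	4.26e-06	9.28e-01	0.043
cg16309866	bmi	trans	-31.83	6.97	4.99e-06	2.37e-01	0.043
cg19120513	bmi	trans	-34.76	7.23	1.53e-06	7.68e-01	0.029
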