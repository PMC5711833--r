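level	management	crop	treatment	resp_control	resp_control_se	heat_control	heat_control_se	caloresp_control	caloresp_control_se	qco2	qco2_se	resp_glucose	resp_glucose_se	heat_glucose	heat_glucose_se	caloresp_glucose	caloresp_glucose_se	n
pooled	CON	NA	CON	34.3	2.3	1.65	0.12	48.4	2.8	0.12	0.009	243.4	4.9	7.44	0.07	30.6	0.5	8
pooled	ORG	NA	ORG	26.5	0.8	1.20	0.04	45.3	1.4	0.09	0.003	229.8	2.6	6.93	0.04	30.2	0.3	8
treatment	CON	ANN	CON-ANN	37.4	4.0	1.76	0.21	47.7	5.3	0.11	0.014	248.1	9.7	7.47	0.12	30.2	1.1	4
treatment	CON	PER	CON-PER	31.2	1.1	1.54	0.11	49.2	2.7	0.13	0.013	238.6	2.2	7.41	0.10	31.0	0.3	4
treatment	ORG	ANN	ORG-ANN	26.1	0.6	1.18	0.04	45.4	2.1	0.09	0.006	229.6	5.2	7.01	0.06	30.6	0.5	4
treatment	ORG	PER	ORG-PER	26.9	1.6	1.22	0.07	45.3	2.0	0.09	0.004	230.1	2.2	6.86	0.04	29.8	0.4	4
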