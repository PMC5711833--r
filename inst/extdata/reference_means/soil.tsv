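level	management	crop	treatment	soc_pct	soc_pct_se	doc	doc_se	no3_n	no3_n_se	po4_p	po4_p_se	ph	ph_se	mbc	mbc_se	bg	bg_se	phox	phox_se	n
pooled	CON	NA	CON	2.91	0.15	61.5	5.1	52.2	3.4	59.6	4.1	5.15	0.08	308.5	26.8	1.31	0.24	0.54	0.03	8
pooled	ORG	NA	ORG	2.72	0.17	45.3	2.2	42.3	1.4	15.5	0.8	5.13	0.13	302.3	13.0	1.04	0.07	0.37	0.07	8
treatment	CON	ANN	CON-ANN	3.09	0.30	61.7	10.1	51.2	7.1	53.7	7.2	5.26	0.14	362.8	32.9	1.66	0.37	0.56	0.05	4
treatment	CON	PER	CON-PER	2.73	0.04	61.3	4.6	53.3	1.1	65.5	2.0	5.03	0.04	254.2	17.5	0.97	0.22	0.52	0.05	4
treatment	ORG	ANN	ORG-ANN	2.89	0.29	46.3	3.4	41.7	1.1	14.8	1.3	4.91	0.15	298.4	17.6	1.10	0.11	0.36	0.11	4
treatment	ORG	PER	ORG-PER	2.55	0.20	44.2	3.3	42.9	2.8	16.2	1.1	5.35	0.16	306.2	21.6	0.98	0.11	0.37	0.11	4
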