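level	management	crop	treatment	rglucose	rglucose_se	rsom	rsom_se	rprimed	rprimed_se	p_glucose_of_total	p_glucose_of_total_se	p_primed_of_total	p_primed_of_total_se	p_primed_of_som	p_primed_of_som_se	n
pooled	CON	NA	CON	173.0	3.1	70.6	3.4	36.2	1.2	71.3	0.9	14.9	0.5	51.4	1.5	8
pooled	ORG	NA	ORG	168.4	2.5	61.5	0.8	34.9	0.5	73.3	0.4	15.4	0.2	56.9	0.9	8
treatment	CON	ANN	CON-ANN	172.5	5.7	75.6	4.3	38.2	1.0	69.8	0.8	15.5	0.6	51.0	2.7	4
treatment	CON	PER	CON-PER	173.6	0.8	63.9	2.6	33.4	1.3	73.3	0.7	14.0	0.6	52.0	0.6	4
treatment	ORG	ANN	ORG-ANN	168.8	4.9	60.8	0.3	34.7	0.7	73.5	0.5	15.3	0.3	57.0	1.1	4
treatment	ORG	PER	ORG-PER	168.0	2.1	62.1	1.5	35.2	0.7	73.0	0.7	15.5	0.3	56.8	1.6	4
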