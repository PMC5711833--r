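level	management	crop	treatment	eta_eff	eta_eff_se	eta_co2	eta_co2_se	eta_soil	eta_soil_se	n
treatment	CON	ANN	CON-ANN	0.684	0.012	0.448	0.013	0.553	0.013	4
treatment	CON	PER	CON-PER	0.675	0.001	0.443	0.003	0.558	0.003	4
treatment	ORG	ANN	ORG-ANN	0.677	0.005	0.435	0.012	0.565	0.012	4
treatment	ORG	PER	ORG-PER	0.687	0.002	0.433	0.005	0.568	0.005	4
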