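descriptor	BM	OU1	OU_regimes	lrt_rejects_simpler
avg_span	0.00	0.35	8.05	FALSE
var_span	3.19	0.00	7.05	TRUE
volume	0.00	9.45	11.76	FALSE
avg_chroma	1.85	0.21	0.00	FALSE
max_chroma	3.63	0.00	6.17	TRUE
brightness	7.28	6.46	0.00	FALSE
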