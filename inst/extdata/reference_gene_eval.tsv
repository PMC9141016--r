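group	species	gene	length	n_sites	site	accuracy_pct	top_k_pct	top_half_pct	n_predicted	fp_pct
human	H. sapiens	LRRC42	31816	7	donor	100	86	100	43	0.11
human	H. sapiens	LRRC42	31816	7	acceptor	100	86	100	52	0.14
human	H. sapiens	CFTR	198641	26	donor	100	73	96	180	0.08
human	H. sapiens	CFTR	198641	26	acceptor	96.15	77	96	259	0.12
human	H. sapiens	BRCA2	94761	26	donor	96.15	73	88	86	0.06
human	H. sapiens	BRCA2	94761	26	acceptor	100	81	96	145	0.13
human	H. sapiens	MTOR	166017	57	donor	100	88	100	210	0.09
human	H. sapiens	MTOR	166017	57	acceptor	100	86	100	310	0.15
other	M. musculus	MTOR	16349	4	donor	100	50	100	25	0.13
other	M. musculus	MTOR	16349	4	acceptor	100	50	100	48	0.27
other	D. rerio	MTOR	254208	57	donor	100	79	98	443	0.15
other	D. rerio	MTOR	254208	57	acceptor	100	79	100	655	0.24
other	D. melanogaster	MTOR	18586	4	donor	100	50	100	71	0.36
other	D. melanogaster	MTOR	18586	4	acceptor	100	50	100	91	0.47
other	A. thaliana	MTOR	18341	22	donor	81.82	55	55	48	0.16
other	A. thaliana	MTOR	18341	22	acceptor	72.73	45	64	78	0.34
other	C. elegans	SMS-2	14058	5	donor	100	60	100	34	0.21
other	C. elegans	SMS-2	14058	5	acceptor	100	60	80	37	0.23
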