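lnc_probe	lnc_symbol	gene_probe	gene_symbol	r	time
214983_at	TTTY15	205000_at	DDX3Y	0.935	2h
214983_at	TTTY15	204410_at	EIF1AY	0.921	2h
214983_at	TTTY15	201909_at	RPS4Y1	0.92	2h
214983_at	TTTY15	206624_at	USP9Y	0.918	2h
214983_at	TTTY15	204409_s_at	EIF1AY	0.907	2h
214983_at	TTTY15	206700_s_at	KDM5D	0.896	2h
214983_at	TTTY15	205001_s_at	DDX3Y	0.892	2h
209917_s_at	TP53TG1	210609_s_at	TP53I3	0.883	2h
209917_s_at	TP53TG1	200885_at	RHOC	0.847	2h
222271_at	---	210609_s_at	TP53I3	0.839	2h
209917_s_at	TP53TG1	215407_s_at	ASTN2	0.835	2h
209917_s_at	TP53TG1	205354_at	GAMT	0.823	2h
209917_s_at	TP53TG1	218180_s_at	EPS8L2	0.82	2h
209917_s_at	TP53TG1	200974_at	ACTA2	0.814	2h
222051_s_at	---	221586_s_at	E2F5	0.809	2h
222271_at	---	200974_at	ACTA2	0.806	2h
209917_s_at	TP53TG1	210224_at	MR1	0.801	2h
214983_at	TTTY15	211149_at	UTY	0.798	2h
209917_s_at	TP53TG1	207565_s_at	MR1	0.797	2h
222271_at	---	215407_s_at	ASTN2	0.796	2h
222271_at	---	200885_at	RHOC	0.793	2h
209917_s_at	TP53TG1	204985_s_at	TRAPPC6A	0.793	2h
222271_at	---	205354_at	GAMT	0.79	2h
209917_s_at	TP53TG1	202949_s_at	FHL2	0.789	2h
222271_at	---	201301_s_at	ANXA4	0.783	2h
209917_s_at	TP53TG1	205531_s_at	GLS2	0.774	2h
209917_s_at	TP53TG1	209498_at	CEACAM1	0.769	2h
209917_s_at	TP53TG1	204034_at	ETHE1	0.766	2h
222271_at	---	203226_s_at	TSPAN31	0.765	2h
209917_s_at	TP53TG1	221666_s_at	PYCARD	0.765	2h
222271_at	---	202949_s_at	FHL2	0.764	2h
215708_s_at	LOC100653079	211804_s_at	CDK2	0.762	6h
222271_at	---	218180_s_at	EPS8L2	0.761	2h
209917_s_at	TP53TG1	212236_x_at	JUP /// KRT17	0.76	2h
209917_s_at	TP53TG1	210223_s_at	MR1	0.76	2h
222271_at	---	210224_at	MR1	0.759	2h
222271_at	---	207566_at	MR1	0.759	2h
214657_s_at	LOC100653017	208899_x_at	ATP6V1D	0.757	2h
209917_s_at	TP53TG1	203650_at	PROCR	0.751	2h
214657_s_at	LOC100653017	33494_at	ETFDH	0.75	2h
222271_at	---	215407_s_at	ASTN2	0.75	6h
213447_at	LOC100506948	221590_s_at	ALDH6A1	0.75	2h
209917_s_at	TP53TG1	203485_at	RTN1	0.75	2h
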