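probe_id	symbol	ensembl_id	biotype
205000_at	DDX3Y	ENSG00000067048	gene
204410_at	EIF1AY	ENSG00000198692	gene
201909_at	RPS4Y1	ENSG00000129824	gene
206624_at	USP9Y	ENSG00000114374	gene
200885_at	RHOC	ENSG00000155366	gene
218180_s_at	EPS8L2	ENSG00000177106	gene
200974_at	ACTA2	ENSG00000107796	gene
204985_s_at	TRAPPC6A	ENSG00000007255	gene
201301_s_at	ANXA4	ENSG00000196975	gene
204034_at	ETHE1	ENSG00000105755	gene
221666_s_at	PYCARD	ENSG00000103490	gene
212236_x_at	JUP	ENSG00000128422	gene
210223_s_at	MR1	ENSG00000153029	gene
33494_at	ETFDH	ENSG00000171503	gene
221590_s_at	ALDH6A1	ENSG00000119711	gene
203485_at	RTN1	ENSG00000139970	gene
209917_s_at	TP53TG1	ENSG00000182165	lncRNA
222051_s_at	---	ENSG00000254208	lncRNA
214657_s_at	LOC100653017	ENSG00000245532	lncRNA
213447_at	LOC100506948	ENSG00000224078	lncRNA
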