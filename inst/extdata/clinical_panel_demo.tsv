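rsID	chrom	pos	ref	alt	significance	condition
rs7794745	7	146489606	A	T	pathogenic	autism susceptibility
rs104894421	13	108861810	C	T	pathogenic	Lig4 syndrome
rs121434442	2	32335000	C	A	pathogenic	hereditary spastic paraplegia
rs4988235	2	136608646	G	A	likely pathogenic	lactose intolerance
rs429358	19	45411941	T	C	pathogenic	Alzheimer disease
rs7412	19	45412079	C	T	pathogenic	Alzheimer disease
rs76763715	1	155205634	T	C	pathogenic	Gaucher disease
rs113993960	7	117199644	A	G	pathogenic	cystic fibrosis
rs1801133	1	11856378	G	A	likely pathogenic	homocystinuria
rs6025	1	169519049	G	A	pathogenic	thrombophilia
rsS0001	3	10000001	C	T	pathogenic	Crohn disease
rsS0002	4	17000002	G	A	likely pathogenic	Parkinson disease
rsS0003	5	24000003	A	C	pathogenic	diabetes
rsS0004	6	31000004	T	G	likely pathogenic	schizophrenia
rsS0005	8	38000005	C	G	pathogenic	ulcerative colitis
rsS0006	3	45000006	C	T	likely pathogenic	Crohn disease
rsS0007	4	52000007	G	A	pathogenic	Parkinson disease
rsS0008	5	59000008	A	C	likely pathogenic	diabetes
rsS0009	6	66000009	T	G	pathogenic	schizophrenia
rsS0010	8	73000010	C	G	likely pathogenic	ulcerative colitis
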