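snp	gene	effect_allele	eaf	variance_explained	beta	se	pval	n
rs4072037	MUC1	T	0.54	0.0057	0.010	0.001	2.0e-36	23829
rs7965584	ATP2B1	A	0.71	0.0025	0.007	0.001	1.1e-16	23829
rs3925584	DCDC5	T	0.55	0.0025	0.006	0.001	5.2e-16	23829
rs11144134	TRPM6	C	0.08	0.0023	0.011	0.001	8.2e-15	23829
rs13146355	SHROOM3	A	0.44	0.0019	0.005	0.001	6.3e-13	23829
rs448378	MDS1	A	0.53	0.0013	0.004	0.001	1.3e-8	23829
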