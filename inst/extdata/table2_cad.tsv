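snp	effect_allele	eaf	beta	se	pval	n
rs4072037	T		-0.015	0.010	0.11	184305
rs10858938	A		-0.016	0.011	0.13	184305
rs3925584	T		-0.016	0.010	0.09	184305
rs11144134	C		0.039	0.019	0.04	184305
rs13146355	A		-0.003	0.010	0.76	184305
rs448378	A		-0.017	0.009	0.06	184305
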