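target_id	proxy_id	r2	target_effect_allele	proxy_effect_allele
rs7965584	rs10858938	0.96	A	A
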