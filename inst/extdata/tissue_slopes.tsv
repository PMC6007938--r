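tissue	dmean_dt	se_mean	dvar_dt	se_var	time_unit	surveyed_length_bp	default_lambda	source
colon	37.2	3.1	985.5	103	year	6000000000	52	Blokzijl et al. 2016, organoid WGS
small_intestine	34.6	6.9	747.3	304	year	6000000000	52	Blokzijl et al. 2016, organoid WGS
liver	30.5	2.1	1564	56	year	6000000000	52	Blokzijl et al. 2016, organoid WGS
prefrontal_cortex	16.2	1.1	7500	965	year	6000000000	52	Lodato et al. 2018, single-neuron WGS
hippocampal_dentate_gyrus	21.8	7.9	15016	6234	year	6000000000	52	Lodato et al. 2018, single-neuron WGS
skin	1.66	0.15	5.23	0.37	year	690000	52	Martincorena et al. 2015, targeted eyelid panel
neurons_development	4.2	1.3	252.2	191	day	6000000000	0.5	Bae et al. 2018, developing-brain single-neuron WGS
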