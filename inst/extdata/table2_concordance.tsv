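method	unit	n_samples	test_only	ref_only	both
DNA variants	variant_event	501	2	47	134
RNA variants	variant_event	102	4	9	72
Fusions	fusion_event	695	0	11	50
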