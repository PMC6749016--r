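sample_id	bethesda	gsc_call	histology	histology_class	partner_variant	tert_variant
T01	II	suspicious	FVPTC	malignant	NRAS:p.Q61K	C228T
T02	IV	suspicious	HCA	benign	HRAS:p.Q61R	C228T
T03	IV	suspicious	HCA	benign	NRAS:p.Q61K	C228T
T04	IV	suspicious	HN	benign	NRAS:p.Q61R	C228T
T05	IV	suspicious	FA	benign	NRAS:p.Q61R	C228T
T06	IV	suspicious	WDT-UMP	benign	NRAS:p.Q61R	C228T
T07	IV	suspicious	PTC	malignant	KRAS:p.Q61R	C228T
T08	IV	suspicious	FC-v	malignant	NRAS:p.Q61R	C228T
T09	V	suspicious	PTC	malignant	BRAF:p.V600E	C228T
T10	V	suspicious	PTC	malignant	BRAF:p.V600E	C228T
T11	VI	suspicious	PTC	malignant	BRAF:p.V600E	C228T
T12	VI	suspicious	PTC-TCV	malignant	BRAF:p.V600E	C228T
T13	VI	suspicious	PTC-TCV	malignant	BRAF:p.V600E	C228T
T14	VI	suspicious	unknown	unknown	BRAF:p.V600E	C228T
T15	VI	suspicious	FC-v	malignant		C228T
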