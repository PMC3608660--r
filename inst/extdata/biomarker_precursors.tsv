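taxon	locus	mz
Sunda_pangolin	biomarker_alpha	2161
anteater	biomarker_alpha	2147
Plesiorycteropus	biomarker_alpha	2129
hairy_armadillo	biomarker_alpha	2131
aardvark	biomarker_alpha	2089
rock_hyrax	biomarker_alpha	2073
golden_mole	biomarker_alpha	2145
elephant_shrew	biomarker_alpha	2161
elephantid	biomarker_alpha	2115
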