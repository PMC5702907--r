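quantity	value
proteome_detected_embryo	2099
proteome_detected_endosperm	786
proteome_common	673
proteome_endosperm_favored	76
proteome_embryo_favored	267
transcriptome_detected_embryo	16998
transcriptome_detected_endosperm	15339
transcriptome_common	14227
metabolome_detected_embryo	123
metabolome_detected_endosperm	118
metabolome_common	117
transcriptome_specific_embryo	2771
transcriptome_specific_endosperm	1112
proteome_specific_endosperm	113
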