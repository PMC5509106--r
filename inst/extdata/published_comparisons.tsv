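comparison	a	b	c	d	alternative
homozygous_vs_heterozygous_knockouts	27	83	14	72	greater
ranked_list_vs_kinome	17	6	25	71	two.sided
ranked_list_vs_transcription_factors	17	6	75	582	two.sided
ranked_list_vs_whole_genome	44	152	235	1765	two.sided
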