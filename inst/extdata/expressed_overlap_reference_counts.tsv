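genotype	total_expressed	core_overlap
H	23516	17691
M	23596	18328
P	23247	17604
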