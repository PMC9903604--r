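genotype	cells_per_0.1mm2
M	138
H	149.7
P	319
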