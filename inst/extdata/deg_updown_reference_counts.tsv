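dap	contrast	n_up	n_down
3	M_vs_H	2134	1781
3	P_vs_H	1248	1399
8	M_vs_H	1499	683
8	P_vs_H	1847	877
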