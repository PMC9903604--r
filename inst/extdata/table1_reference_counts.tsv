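dap	class_label	category	n
3	trans_up_M_gt_P	transgressive_up	15
3	trans_up_M_eq_P	transgressive_up	3
3	trans_up_M_lt_P	transgressive_up	4
3	trans_down_M_gt_P	transgressive_down	70
3	trans_down_M_eq_P	transgressive_down	12
3	trans_down_M_lt_P	transgressive_down	0
3	ELD_M_high	ELD_M	622
3	ELD_M_low	ELD_M	790
3	ELD_P_high	ELD_P	1385
3	ELD_P_low	ELD_P	529
3	additive_M_gt_P	additive	1075
3	additive_M_lt_P	additive	1594
3	additive_conserved	additive	17045
8	trans_up_M_gt_P	transgressive_up	12
8	trans_up_M_eq_P	transgressive_up	3
8	trans_up_M_lt_P	transgressive_up	2
8	trans_down_M_gt_P	transgressive_down	29
8	trans_down_M_eq_P	transgressive_down	3
8	trans_down_M_lt_P	transgressive_down	0
8	ELD_M_high	ELD_M	1360
8	ELD_M_low	ELD_M	403
8	ELD_P_high	ELD_P	998
8	ELD_P_low	ELD_P	239
8	additive_M_gt_P	additive	1129
8	additive_M_lt_P	additive	1432
8	additive_conserved	additive	16899
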