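contrast	source	n_hits	n_tested
AD_vs_ctrl	AD_gwas	16	79
ADLB_vs_ctrl	AD_gwas	19	79
ADLB_vs_ctrl	PD_gwas	2	76
LB_vs_ctrl	PD_gwas	3	76
ADLB_vs_AD	PD_gwas	2	76
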