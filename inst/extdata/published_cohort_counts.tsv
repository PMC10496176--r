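name	value
ADpLBp_n	1072
ADpLBm_n	2492
ADmLBp_n	158
ADmLBm_n	1263
preliminary_n	5254
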