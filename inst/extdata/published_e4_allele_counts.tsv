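category	subset	e4_count	allele_total
AD+LB+	overall	744	2144
AD+LB-	overall	1685	4984
AD-LB+	overall	28	316
AD-LB-	overall	249	2526
AD+LB+	NACC	662	1702
AD+LB-	NACC	1492	3946
AD-LB+	NACC	20	168
AD-LB-	NACC	166	1448
AD+LB+	Rush	82	442
AD+LB-	Rush	193	1038
AD-LB+	Rush	8	148
AD-LB-	Rush	83	1078
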