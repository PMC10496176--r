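rsid	chrom	pos	effect_allele	other_allele	direction	source	label
rs9000001	1	1100000	A	G	+	AD_gwas	GENE01
rs9000002	1	1200000	C	T	+	AD_gwas	GENE02
rs9000003	2	1100000	G	A	-	AD_gwas	GENE03
rs9000004	3	1100000	T	C	+	AD_gwas	GENE04
rs9000005	4	1100000	A	C	+	AD_gwas	GENE05
rs9000006	5	1100000	C	G	-	AD_gwas	GENE06
rs9000007	6	1100000	G	T	+	PD_gwas	GENE07
rs9000008	7	1100000	T	A	+	PD_gwas	GENE08
rs9000009	8	1100000	A	G	-	PD_gwas	GENE09
rs9000010	9	1100000	C	T	+	PD_gwas	GENE10
rs9000011	10	1100000	G	A	+	PD_gwas	GENE11
rs9000012	11	1100000	T	C	-	PD_gwas	GENE12
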