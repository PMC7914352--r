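table_id	row_label	col_label	count
hla_normal_by_subtype	hla_normal	immune_rich	10
hla_normal_by_subtype	hla_normal	other	3
hla_normal_by_subtype	hla_down	immune_rich	10
hla_normal_by_subtype	hla_down	other	31
mskcc_rnaseq	class_1	immune_poor	0
mskcc_rnaseq	class_1	immune_intermediate	3
mskcc_rnaseq	class_1	immune_rich	1
mskcc_rnaseq	class_2	immune_poor	2
mskcc_rnaseq	class_2	immune_intermediate	0
mskcc_rnaseq	class_2	immune_rich	5
mskcc_rnaseq	class_3	immune_poor	2
mskcc_rnaseq	class_3	immune_intermediate	5
mskcc_rnaseq	class_3	immune_rich	2
relapse_rnaseq	relapse	immune_poor	2
relapse_rnaseq	relapse	immune_intermediate	7
relapse_rnaseq	relapse	immune_rich	3
relapse_rnaseq	no_relapse	immune_poor	2
relapse_rnaseq	no_relapse	immune_intermediate	1
relapse_rnaseq	no_relapse	immune_rich	5
phenotype_rnaseq	non_gc	immune_poor	4
phenotype_rnaseq	non_gc	immune_intermediate	5
phenotype_rnaseq	non_gc	immune_rich	6
phenotype_rnaseq	gc	immune_poor	0
phenotype_rnaseq	gc	immune_intermediate	2
phenotype_rnaseq	gc	immune_rich	2
phenotype_rnaseq	unclassified	immune_poor	0
phenotype_rnaseq	unclassified	immune_intermediate	1
phenotype_rnaseq	unclassified	immune_rich	0
cmyc_rnaseq	positive	immune_poor	2
cmyc_rnaseq	positive	immune_intermediate	3
cmyc_rnaseq	positive	immune_rich	4
cmyc_rnaseq	negative	immune_poor	2
cmyc_rnaseq	negative	immune_intermediate	5
cmyc_rnaseq	negative	immune_rich	4
cmyc_bcl2_rnaseq	positive	immune_poor	2
cmyc_bcl2_rnaseq	positive	immune_intermediate	3
cmyc_bcl2_rnaseq	positive	immune_rich	3
cmyc_bcl2_rnaseq	negative	immune_poor	2
cmyc_bcl2_rnaseq	negative	immune_intermediate	5
cmyc_bcl2_rnaseq	negative	immune_rich	5
bcl6_rnaseq	positive	immune_poor	4
bcl6_rnaseq	positive	immune_intermediate	5
bcl6_rnaseq	positive	immune_rich	8
bcl6_rnaseq	negative	immune_poor	0
bcl6_rnaseq	negative	immune_intermediate	3
bcl6_rnaseq	negative	immune_rich	0
sex_rnaseq	male	immune_poor	2
sex_rnaseq	male	immune_intermediate	4
sex_rnaseq	male	immune_rich	4
sex_rnaseq	female	immune_poor	2
sex_rnaseq	female	immune_intermediate	4
sex_rnaseq	female	immune_rich	4
sex_microarray	male	immune_poor	4
sex_microarray	male	immune_intermediate	8
sex_microarray	male	immune_rich	7
sex_microarray	female	immune_poor	2
sex_microarray	female	immune_intermediate	8
sex_microarray	female	immune_rich	5
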