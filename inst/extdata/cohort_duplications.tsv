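duplicated_region	duplicated_seq	insert_size	insert_pos_start	insert_pos_end	other_ets_variants	age	race	sex	cancer_type	tumor_type	dataset
c.-100_-79	GGGCGGGGCCGCGGAAAGGAAG	22	1295182	1295183	NA	NA	NA	NA	Glioblastoma Multiforme	NA	Pierini et al.
c.-100_-79	GGGCGGGGCCGCGGAAAGGAAG	22	1295182	1295183	None	54	NA	Male	Glioblastoma Multiforme	NA	UCSF500
c.-100_-79	GGGCGGGGCCGCGGAAAGGAAG	22	1295182	1295183	G228A	29	NA	Female	Squamous Cell Carcinoma	Metastasis	UCSF500
c.-100_-79	GGGCGGGGCCGCGGAAAGGAAG	22	1295182	1295183	None	68	White	Male	Duodenal Adenocarcinoma	Metastasis	GENIE
c.-100_-79	GGGCGGGGCCGCGGAAAGGAAG	22	1295182	1295183	None	48	NA	Male	Glioblastoma Multiforme	Primary	UCSF500
c.-100_-79	GGGCGGGGCCGCGGAAAGGAAG	22	1295182	1295183	None	48	NA	Male	Glioblastoma Multiforme	Primary	UCSF500
c.-100_-79	GGGCGGGGCCGCGGAAAGGAAG	22	1295182	1295183	None	48	NA	Male	Glioblastoma Multiforme	Recurrent	UCSF500
c.-104_-83	GGGGCCGCGGAAAGGAAGGGGA	22	1295186	1295187	None	42	Asian	Male	Oral Cavity Squamous Cell Carcinoma	Metastasis	GENIE
c.-104_-83	GGGGCCGCGGAAAGGAAGGGGA	22	1295186	1295187	None	50	White	Male	Bladder Urothelial Carcinoma	Primary	GENIE
c.-104_-83	GGGGCCGCGGAAAGGAAGGGGA	22	1295186	1295187	None	68	Black	Male	Hepatocellular Carcinoma	Primary	GENIE
c.-104_-83	GGGGCCGCGGAAAGGAAGGGGA	22	1295186	1295187	NA	NA	NA	NA	Papillary Thyroid Cancer	NA	Panebianco et al.
c.-110_-89	GCGGAAAGGAAGGGGAGGGGCT	22	1295192	1295193	None	48	Asian	Female	Malignant Phyllodes Tumor of the Breast	Primary	GENIE
c.-110_-89	GCGGAAAGGAAGGGGAGGGGCT	22	1295192	1295193	None	64	White	Male	Glioblastoma Multiforme	Primary	GENIE
c.-110_-89	GCGGAAAGGAAGGGGAGGGGCT	22	1295192	1295193	None	65	NA	Male	Glioblastoma Multiforme	Primary	GENIE
c.-110_-89	GCGGAAAGGAAGGGGAGGGGCTA	23	1295192	1295193	None	69	White	Female	Papillary Thyroid Cancer	Metastasis	GENIE
c.-110_-89	GCGGAAAGGAAGGGGAGGGGCTA	23	1295192	1295193	None	72	White	Female	Poorly Differentiated Thyroid Cancer	Metastasis	GENIE
c.-110_-89	GCGGAAAGGAAGGGGAGGGGCT	22	1295192	1295193	NA	NA	NA	NA	Glioblastoma Multiforme	NA	Pierini et al.
c.-116_-96	GGAAGGGGAGGGGCTGGGAGG	21	1295199	1295200	None	64	White	Male	Hepatocellular Carcinoma	Primary	GENIE
c.-120_-96	GGAAGGGGAGGGGCTGGGAGGGCCC	25	1295199	1295200	None	80	NA	Female	Poorly Differentiated Thyroid Cancer	NA	UCSF500
c.-120_-96	GGAAGGGGAGGGGCTGGGAGGGCCC	25	1295199	1295200	None	68	White	Male	Hepatocellular Carcinoma	Primary	GENIE
c.-125_-106	GGGGCTGGGCTGGGAGGGCCCGGAA	25	1295228	1295229	G228A	69	White	Male	Bladder Urothelial Carcinoma	Metastasis	GENIE
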