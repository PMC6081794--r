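pathway	product	route	ec	step	production_specific	tentative	taxa
acetate_direct	acetate	direct from pyruvate (poxB)	1.2.5.1	1	TRUE	FALSE	Clostridiales;Prevotellaceae
acetate_acetyl_coa	acetate	via acetyl-CoA	1.2.7.1	1	FALSE	FALSE	Prevotellaceae;Clostridiales;Negativicutes
acetate_acetyl_coa	acetate	via acetyl-CoA	2.8.3.8	2	TRUE	TRUE	Prevotellaceae;Clostridiales;Negativicutes
acetate_acetyl_p	acetate	via acetyl-CoA and acetyl-P	1.2.7.1	1	FALSE	FALSE	Prevotellaceae;Clostridiales;Negativicutes
acetate_acetyl_p	acetate	via acetyl-CoA and acetyl-P	2.3.1.8	2	FALSE	FALSE	Prevotellaceae;Clostridiales;Negativicutes
acetate_acetyl_p	acetate	via acetyl-CoA and acetyl-P	2.7.2.1	3	TRUE	FALSE	Prevotellaceae;Clostridiales;Negativicutes
propionate_succinate	propionate	succinate pathway	5.4.99.2	1	FALSE	FALSE	Prevotellaceae;Clostridiales;Negativicutes
propionate_succinate	propionate	succinate pathway	5.1.99.1	2	FALSE	TRUE	Prevotellaceae;Clostridiales;Negativicutes
propionate_succinate	propionate	succinate pathway	4.1.1.41	3	TRUE	FALSE	Prevotellaceae;Clostridiales;Negativicutes
propionate_succinate	propionate	succinate pathway	2.8.3.1	4	FALSE	TRUE	Prevotellaceae;Clostridiales;Negativicutes
propionate_acrylate	propionate	acrylate pathway	2.8.3.1	1	FALSE	TRUE	Negativicutes;Clostridiales
propionate_acrylate	propionate	acrylate pathway	4.2.1.54	2	FALSE	FALSE	Negativicutes;Clostridiales
propionate_acrylate	propionate	acrylate pathway	1.3.8.7	3	TRUE	FALSE	Negativicutes;Clostridiales
butyrate_kinase	butyrate	butyrate kinase pathway	2.3.1.9	1	FALSE	FALSE	Clostridiales
butyrate_kinase	butyrate	butyrate kinase pathway	1.1.1.157	2	FALSE	FALSE	Clostridiales
butyrate_kinase	butyrate	butyrate kinase pathway	4.2.1.55	3	FALSE	FALSE	Clostridiales
butyrate_kinase	butyrate	butyrate kinase pathway	1.3.8.1	4	FALSE	FALSE	Clostridiales
butyrate_kinase	butyrate	butyrate kinase pathway	2.3.1.19	5	FALSE	FALSE	Clostridiales
butyrate_kinase	butyrate	butyrate kinase pathway	2.7.2.7	6	TRUE	FALSE	Clostridiales
butyrate_coa_transferase	butyrate	butyryl-CoA:acetate CoA-transferase pathway	2.3.1.9	1	FALSE	FALSE	Negativicutes
butyrate_coa_transferase	butyrate	butyryl-CoA:acetate CoA-transferase pathway	1.1.1.157	2	FALSE	FALSE	Negativicutes
butyrate_coa_transferase	butyrate	butyryl-CoA:acetate CoA-transferase pathway	4.2.1.55	3	FALSE	FALSE	Negativicutes
butyrate_coa_transferase	butyrate	butyryl-CoA:acetate CoA-transferase pathway	1.3.8.1	4	FALSE	FALSE	Negativicutes
butyrate_coa_transferase	butyrate	butyryl-CoA:acetate CoA-transferase pathway	2.8.3.8	5	TRUE	FALSE	Negativicutes
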