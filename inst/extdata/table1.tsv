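compound	class	log2_ratio	fdr	specific_tissue
gamma-tocopherol	Apolar	NA	NA	embryo
Maltotriose	Carbohydrate	NA	NA	embryo
Ascorbate	Organic acids	NA	NA	endosperm
Feruoylquinic acid	Organic acids	NA	NA	embryo
Adenosine-5-P	Purine_Pyrimidine	NA	NA	embryo
Galactinol_isomer_1	Sugar alcohol	NA	NA	embryo
Galactinol_isomer_2	Sugar alcohol	NA	NA	embryo
4-hydroxyproline	Amino acids	1.95	0.05	
Alanine	Amino acids	0.88	0.04	
beta-Alanine	Amino acids	1.76	0.03	
3-cyano-alanine	Amino acids	3.31	0.03	
Cystein	Amino acids	1.77	0.05	
4-Aminobutyrate (GABA)	Amino acids	2.29	0.01	
Glutamine	Amino acids	3.00	0.01	
Isoleucine	Amino acids	2.30	0.04	
Leucine	Amino acids	2.21	0.03	
Lysine	Amino acids	1.32	0.00	
Ornithine	Amino acids	0.84	0.03	
Phenylalanine	Amino acids	2.57	0.03	
Pyroglutamate	Amino acids	0.97	0.03	
Serine	Amino acids	2.05	0.03	
Threonine	Amino acids	1.59	0.04	
Tryptophan	Amino acids	1.20	0.01	
Valine	Amino acids	2.39	0.04	
alpha-Tocopherol	Apolar	-2.55	0.03	
beta-Sitosterol	Apolar	2.57	0.00	
Campesterol	Apolar	1.72	0.00	
Monopalmitin	Apolar	3.83	0.03	
Monostearin	Apolar	4.62	0.02	
Stigmasterol	Apolar	3.18	0.00	
N-acetylmannosamine	Other	2.49	0.02	
Arabinose	Carbohydrate	4.38	0.02	
Cellobiose	Carbohydrate	1.95	0.03	
Galactose	Carbohydrate	5.64	0.02	
Glucopyranose	Carbohydrate	4.30	0.02	
Mannose	Carbohydrate	1.54	0.01	
Melibiose	Carbohydrate	1.49	0.01	
Ribose	Carbohydrate	5.07	0.01	
Sedoheptulose	Carbohydrate	3.56	0.02	
Trehalose	Carbohydrate	1.53	0.00	
Xylose	Carbohydrate	4.42	0.02	
Raffinose	Carbohydrate	-0.76	0.02	
Sucrose	Carbohydrate	0.98	0.01	
Linoleic acid	Fatty acids	4.76	0.01	
Linolenic acid	Fatty acids	4.61	0.02	
Caffeate	Organic acids	4.73	0.03	
Citrate	Organic acids	-1.24	0.01	
Erythronate	Organic acids	3.57	0.05	
Fumarate	Organic acids	3.20	0.05	
4-hydroxybutanoate	Organic acids	5.34	0.01	
Glucaric acid	Organic acids	-2.69	0.01	
Gluconate	Organic acids	1.96	0.03	
Glycerate	Organic acids	3.80	0.03	
Glycolate	Organic acids	4.57	0.03	
Malate	Organic acids	2.77	0.01	
Maleate	Organic acids	3.90	0.01	
Malonate	Organic acids	2.35	0.05	
Nicotinate	Organic acids	2.11	0.03	
Phosphate	Organic acids	1.15	0.01	
Pipecolate	Organic acids	0.68	0.01	
Salicylate	Organic acids	4.03	0.05	
Sinapinate	Organic acids	3.90	0.03	
Sinapinate-trans	Organic acids	4.01	0.01	
Succinate	Organic acids	3.28	0.03	
Threonate	Organic acids	1.50	0.00	
Spermidine	Polyamine	2.76	0.01	
Guanine	Purine_Pyrimidine	4.31	0.03	
Uracil	Purine_Pyrimidine	3.62	0.04	
Erythritol	Sugar alcohol	3.59	0.00	
Glycerol	Sugar alcohol	4.19	0.03	
Glycerol-2-P	Sugar alcohol	1.56	0.01	
Glycerol-3-P	Sugar alcohol	0.56	0.01	
Inositol_isomer_3	Sugar alcohol	2.15	0.03	
Inositol_isomer_4	Sugar alcohol	1.59	0.01	
Inositol_isomer_5	Sugar alcohol	2.66	0.03	
Inositol-1-P	Sugar alcohol	3.15	0.03	
Mannitol	Sugar alcohol	3.98	0.03	
Digalactosylglycerol	Sugar alcohol	-0.61	0.00	
Galactosylglycerol	Sugar alcohol	4.38	0.03	
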