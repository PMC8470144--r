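metabolite	fold_change	univariate_fdr	vip_comp1	mda	sam_fdr
Betaine	0.664	0.00215	1.413	0.0086	0.0077
4-Pyridoxic Acid	0.725	0.0376	1.13	0.00133	0.033
Phosphocreatine	1.317	0.000906	1.174	0.00527	0.0141
Aminoimidazole Carboxamide Ribonucleotide	0.63	0.0283	1.403	0.00167	0.0141
Glutathione	3.743	0.000442	2.583	0.00627	0
Acetoacetate	0.596	0.000101	1.662	0.0072	0.00423
2-Oxobutanoate	0.593	0.000101	1.662	0.00333	0.00423
GTP	1.92	0.0267	1.653	0.00427	0.0077
N-Carbamoyl-L-Aspartate	0.822	0.0015	1.604	0.0068	0.00506
D-Gluconate	0.725	0.00543	1.239	0.00227	0.0152
Homoserine	0.598	0.00421	1.581	0.00547	0.00568
Acetyl-CoA	0.044	0.000107	4.158	0.00393	0
N-Acetyl-L-Aspartic Acid	2.249	9.87e-06	2.106	0.00467	0
Adenylosuccinate	0.534	0.0061	1.746	0.00577	0.00506
GDP	2.054	0.0316	1.693	0.00433	0.0077
5-Phosphoribosyl-1-Pyrophosphate	1.758	0.000906	1.691	0.00227	0.00449
Cytidine	0.16	0.000242	3.065	0.00713	0
S-Ribosyl-L-Homocysteine	1.416	0.0158	1.261	0.00667	0.016
Acetylcarnitine DL	0.666	0.0015	1.428	0.00233	0.00736
N-Acetyl-Glutamine	1.608	0.0148	1.462	0.00173	0.0113
Deoxyguanosine	0.563	0.00364	1.658	0.00247	0.00506
Betaine Aldehyde	0.702	0.00421	1.312	0.0048	0.0121
1,3-Diphopshateglycerate	1.843	0.0256	1.615	0.00413	0.00898
Homocysteine	1.377	0.00174	1.268	0.00573	0.0121
dAMP	1.373	0.00266	1.238	0.0054	0.0141
D-Glucono-1,5-Lactone-6-Phosphate	0.7	0.0118	1.27	0.0018	0.0155
Homocysteic Acid	0.617	0.0217	1.418	0.00147	0.0132
Cystine	0.215	0.0165	2.371	0.0048	0.00385
4-Aminobutyrate	0.741	0.00186	1.218	0.00787	0.0141
Putrescine	0.528	0.00226	1.76	0.0076	0.00449
Ornithine	1.405	1.04e-05	1.36	0.00777	0.00506
Coenzyme A	4.07	0.0165	2.276	0.00413	0.00423
2,3-Diphosphoglyceric Acid	1.926	0.0121	1.698	0.0048	0.00558
Hypoxanthine	0.251	4.76e-07	2.77	0.00753	0
Citrate	1.399	0.000156	1.329	0.00927	0.00736
Allantoate	0.625	0.000242	1.567	0.001	0.00474
1-Methyladenosine	0.615	0.00169	1.543	0.00233	0.00506
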