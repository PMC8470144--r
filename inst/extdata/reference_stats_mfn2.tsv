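metabolite	fold_change	univariate_fdr	vip_comp1	mda	sam_fdr
CDP	0.687	0.0278	1.287	0.000667	0.0321
Carbamoyl Phosphate	1.251	0.0261	1.008	0.0018	0.0504
Asparagine	1.264	0.0113	1.065	0.0034	0.0374
D-Glucosamine-1-Phosphate	0.443	0.0261	1.909	0.00233	0.0137
S-Adenosyl-L-Methioninamine	0.329	0.00607	2.379	0.00227	0.00484
2-Dehydro-D-Gluconate	0.686	0.00286	1.396	0.00993	0.0235
Indole	1.363	0.00286	1.267	0.003	0.0282
Citrulline	1.27	0.00184	1.135	0.00553	0.0314
GTP	1.337	0.016	1.156	0.001	0.0355
Arginosuccinic Acid	1.584	0.00257	1.561	0.00593	0.0142
GMP	1.419	0.0159	1.303	0.0018	0.0299
2-Aminooctanoic Acid	0.67	0.00184	1.463	0.0036	0.0185
Arginine	1.254	0.00228	1.101	0.0034	0.0332
Purine	1.265	0.00414	1.099	0.005	0.0341
NADPH	0.185	0.0159	2.729	0.00263	0.00484
O8P-O1P	1.378	0.00576	1.276	0.00653	0.0291
L-Arginino-Succinate	1.496	0.000871	1.508	0.00844	0.0137
Alanine	0.548	0.000871	1.839	0.0148	0.00484
5-Phosphoribosyl-1-Pyrophosphate	1.598	0.0259	1.458	0.000667	0.028
S-Ribosyl-L-Homocysteine	0.391	0.0162	2.049	0.00313	0.00916
Acetylcarnitine DL	0.535	0.00129	1.827	0.00327	0.00484
2-Hydroxy-2-Methylbutanedioic Acid	1.402	0.0159	1.282	0.00233	0.0299
Glutathione Disulfide	1.314	0.0198	1.097	0.00893	0.0374
Phenylalanine	1.283	0.000891	1.172	0.0123	0.0292
dTMP	1.118	0.0203	1.441	0.0056	0.028
NADH	1.246	0.0125	1.434	0.000667	0.026
Nicotinamide Ribotide	2.05	0.00286	1.92	0.00233	0.00484
Uridine	1.401	0.0278	1.229	0.0014	0.0341
Indoleacrylic Acid	1.317	0.0115	1.168	0.0048	0.0341
Tryptophan	1.374	0.00184	1.303	0.00673	0.026
3-Phosphoglycerate	0.689	0.0128	1.336	0.00513	0.0291
N-Acetyl-Glucosamine	0.663	0.0243	1.343	0.0013	0.0299
Sarcosine	0.582	0.000223	1.763	0.0058	0.00484
Tyrosine	1.259	0.00889	1.066	0.0117	0.0372
Aspartate	0.759	0.000467	1.25	0.00513	0.026
D-Glucono-1,5-Lactone-6-Phosphate	0.338	0.00752	2.217	0.0036	0.00484
Methylcysteine	1.333	0.001	1.256	0.002	0.026
Glycerophosphocholine	1.321	0.0161	1.138	0.00427	0.0355
Putrescine	23.644	0.00714	3.693	0.00333	0
Ornithine	0.394	0.000871	2.259	0.00633	0.00484
Trehalose-6-Phosphate	0.578	0.0203	1.598	0.00107	0.0235
Carnitine	0.748	0.00414	1.231	0.00527	0.0293
Pantothenate	1.474	0.0162	1.327	0.00393	0.0293
Serine	1.26	0.00257	1.115	0.0044	0.0329
Guanosine	1.721	0.0304	1.53	8e-04	0.026
Inosine	2.15	0.000967	2.047	0.00993	0.00484
Orotidine-5-Phosphate	1.499	0.0279	1.355	0.00233	0.0299
Thiamine-Phosphate	2.167	0.00576	1.927	0.0058	0.0072
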