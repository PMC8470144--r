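metabolite	fold_change	univariate_fdr	vip_comp1	mda	sam_fdr
Citrate-Isocitrate	0.654	2.7e-05	1.16	0.00397	0.00757
CDP	1.771	0.00123	1.304	0.00513	0.00732
Carbamoyl Phosphate	2.619	5.46e-05	1.742	0.007	0.00111
Fumarate	2.787	2.11e-08	1.846	0.00251	0.000255
Aminoimidazole Carboxamide Ribonucleotide	0.526	0.00479	1.358	0.0106	0.00741
Choline	0.534	0.012	1.277	0.002	0.00862
Orotate	15.739	0.00583	2.569	8e-04	0.000727
Thiamine Pyrophosphate	1.781	0.00286	1.267	0.00343	0.00757
Acetoacetate	0.587	0.0228	1.15	0.00227	0.0155
Phosphorylcholine	0.373	1.28e-09	1.814	0.0115	0.000255
Isocitrate	0.477	0.00499	1.416	0.00213	0.00732
Deoxyadenosine	0.288	0.0186	1.907	9e-04	0.00573
1-Methyladenosine	1.883	0.0036	1.36	0.00667	0.00732
2-Aminooctanoic Acid	1.812	0.00499	1.267	0.00574	0.00764
D-Gluconate	1.999	3.9e-06	1.507	0.00573	0.0034
2-Keto-Isovalerate	2.868	1.39e-08	1.873	0.00574	0.000255
Acetyl-CoA	4.344	0.0167	2.061	8e-04	0.0042
N-Carbamoyl-L-Aspartate	51.968	2.86e-10	3.627	0.0074	0
Cellobiose	0.134	0.00499	2.296	0.00547	0.00102
O8P-O1P	1.511	0.000757	1.119	0.00853	0.00911
Thiamine-Phosphate	1.822	0.0487	1.147	5e-04	0.0188
Creatine	1.814	3.86e-06	1.394	0.00433	0.00544
CDP-Ethanolamine	7.035	0.000145	2.473	0.005	0
Acetylcarnitine DL	1.841	0.00338	1.295	0.00413	0.00757
Aconitate	0.542	2.7e-05	1.399	0.00903	0.00573
Shikimate	0.367	0.000181	1.781	0.00527	0.0012
Anthranilate	1.485	0.0212	1.014	0.00233	0.0212
Uridine	3.66	9.62e-05	2.051	0.00114	0.000727
2-Isopropylmalic Acid	81.792	1.87e-11	3.844	0.00953	0
CMP	3.127	3.9e-06	1.91	0.00407	0.000424
CDP-Choline	8.569	0.000571	2.438	0.0036	0.000255
Deoxyguanosine	0.507	0.00209	1.402	0.0026	0.00732
Citraconic Acid	0.639	0.000181	1.173	0.00473	0.00757
N-acetyl-glucosamine	1.556	0.00859	1.109	0.00547	0.014
Glycerophosphocholine	1.606	3.48e-05	1.225	0.004	0.00732
2-Oxo-4-Methylthiobutanoate	0.462	0.0438	1.405	0.0014	0.00941
Histidinol	1.546	0.0244	1.021	0.0032	0.0212
4-Aminobutyrate	1.948	0.000426	1.417	0.0046	0.00611
Dihydroorotate	7.471	3.97e-07	2.569	0.0076	0
UDP	1.854	0.00422	1.315	0.0066	0.00757
Itaconic Acid	0.688	0.000804	1.05	0.00607	0.0123
Maleic Acid	2.836	1.41e-07	1.86	0.0048	0.000424
dCDP	1.194	0.00578	1.31	0.00467	0.00764
N-Acetyl-Glucosamine-1-Phosphate	2.279	0.00499	1.567	8e-04	0.00646
Aspartate	3.759	4.98e-08	2.087	0.0108	0
Allantoate	158.36	3.66e-12	4.12	0.0084	0
Guanosine	2.804	0.00239	1.768	0.005	0.00389
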