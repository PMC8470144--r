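# Bundled data files

* `reference_stats_mfn2.tsv`, `reference_stats_sgdrp1.tsv`,
  `reference_stats_leflunomide.tsv` — published per-metabolite consensus
  statistics (fold change, univariate BH FDR, component-1 VIP, raw MDA,
  SAM FDR) for the three mitochondrial-fusion induction conditions
  (Tet-On Mfn2 overexpression, CRISPR Drp1 knockout, leflunomide
  treatment) in KPC pancreatic-cancer cells. Used to exercise the
  threshold gates on realistic printed values.
* `synthetic_pathways.json` — hand-built synthetic pathway library (12
  pathways, 147 invented KEGG-style compound IDs with synonyms, directed
  edges). Not real KEGG content; made for tests and examples.
* `synthetic_chain.kgml` — minimal hand-written KGML file (three
  compounds, one irreversible and one reversible reaction) for the KGML
  reader tests.
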