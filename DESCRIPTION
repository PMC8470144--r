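Package: consensusmet
Title: Consensus Feature Selection and Topology-Aware Pathway Analysis for
    Untargeted Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for comparative two-group untargeted
    metabolomics. Implements strict any-missing metabolite filtering,
    control-referenced normalization, log transformation and Pareto scaling;
    four independent feature-selection models (FDR-adjusted two-sample
    t-tests, significance analysis of microarrays with permutation-estimated
    FDR and delta-band calling, NIPALS PLS-DA with variable importance in
    projection, and random-forest out-of-bag permutation importance); a
    four-way consensus intersection of the discriminant lists; and
    compound-set pathway analysis with a permutation Global Test,
    out-degree-centrality impact scores, a percent-affected score and
    FDR/impact/percent-affected filtering. Includes a synthetic two-group
    panel generator with planted effects, abundance-dependent missingness
    and a cell-count nuisance so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    randomForest,
    xml2
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
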