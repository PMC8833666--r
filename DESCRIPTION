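Package: SelenoNet
Title: Interactome Merging, Hub Centrality and Clinical Statistics for
    Selenoprotein Networks in Triple-Negative Breast Cancer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds the network-analysis pipeline used to nominate
    coordinated biomarkers in triple-negative breast cancer (TNBC):
    merging of multi-source protein-protein interaction edge lists into
    one undirected simple interactome with per-edge provenance,
    fold-change based differential-expression gene selection,
    seed-family sub-network extraction with first/second-order
    neighborhoods, eleven-measure topological hub scoring (degree, MNC,
    DMNC, MCC, EPC, BottleNeck, eccentricity, harmonic closeness,
    radiality, betweenness, stress) with consensus hub ranking and
    small-world network statistics, 2^-ddCq relative quantification of
    qPCR data, immunohistochemistry grade/intensity statistics with
    Pearson correlation, and Kaplan-Meier/log-rank comparison of a
    combined two-gene expression split. A synthetic-data module
    generates every pipeline input with recorded ground truth
    (planted hubs, planted log2 fold changes, latent correlations,
    hazard ratios) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    withr,
    survival,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
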