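Package: trmet
Title: Transcriptional-Regulator Activity Inference and TR-Metabolite
    Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A computational framework linking transcriptional-regulator
    (TR) activity to metabolome profiles in panels of adherent cell lines.
    Provides cell-number-regression normalization of untargeted
    flow-injection metabolomics intensities (plate-factor correction,
    per-cell abundance slopes, volume correction, Z-scoring, m/z
    annotation), bootstrapped network-component-analysis inference of TR
    activities from gene expression and a signed regulatory network,
    Spearman TR-metabolite association networks with bootstrap FDR control,
    shortest-path distance tests on a bipartite stoichiometric network,
    hypergeometric and iterative-rank pathway enrichment with Storey
    q-values, dot-product scoring of TRs against flux, knockdown, patient
    and drug-sensitivity data, and an ensemble scan of saturable
    metabolite/kinase effector models of TR activity. A seeded synthetic
    data generator emulates the full study design so the pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
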