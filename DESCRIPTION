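Package: lecanet
Title: Ancestral Protein Interactome Inference from Co-Fractionation
    Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to infer an ancestral (last eukaryotic common ancestor)
    protein interactome from multi-species proteomics evidence and to use
    the resulting network for disease-gene prioritization. Implements Dollo
    parsimony calling of ancestral orthogroups on a species tree,
    assembly and filtering of multi-experiment co-elution matrices,
    co-elution and co-purification feature engineering for candidate
    protein pairs, supervised interaction scoring with complex-withheld
    cross-validation and false-discovery-rate calibration, a random-walk
    (walktrap) community detection hierarchy with per-cluster evaluation,
    conservation annotation by eukaryotic supergroup, and cross-validated
    network guilt-by-association with AUROC-based disease ranking. A
    synthetic-data generator with planted complexes, Poisson count noise,
    and single-gain/multiple-loss gene evolution makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
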