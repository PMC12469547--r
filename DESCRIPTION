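Package: metabloc
Title: Multiblock Differential Analysis of Urinary Metabolomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end differential analysis of two-group urinary
    metabolomics intensity matrices: probabilistic quotient normalization
    and autoscaling, per-metabolite Mann-Whitney screening with
    Benjamini-Hochberg correction and volcano classification, NIPALS
    PLS-DA and OPLS-DA latent modelling with cross-validated Q2Y,
    permutation validation and VIP scores, hierarchical multiblock
    functional scoring with random-forest block selection, and
    group-specific shrinkage partial-correlation differential networks
    with betweenness-centrality hub selection. Includes a synthetic-data
    generator with known ground truth (planted fold changes, dilution
    factors, block structure and group-specific block dependence) so the
    whole pipeline is testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
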