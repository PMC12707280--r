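Package: germnet
Title: Cross-Kingdom Co-Expression and Trait Association for Host-Microbiome Transcriptomics
Version: 0.1.0
Authors@R:
    person("GERMs", "Pipeline Maintainers", email = "germnet@example.org",
           role = c("aut", "cre"))
Description: Joint analysis of plant and rhizosphere-microbiome expression
    profiles from a factorial (genotype x soil x temperature) design:
    compositional preprocessing (low-expression and taxon filters, relative
    abundance, centered log-ratio, median-of-ratios size factors, rarefaction,
    pathway aggregation), permutation-based community statistics (PERMANOVA,
    Mantel, PCA, platform slope comparison), Fisher-z differential correlation
    between plant genes and microbial features across temperature conditions
    with Benjamini-Hochberg control, bipartite host-microbe network
    extraction, and a three-method (differential correlation, elastic net,
    random forest) consensus for trait-associated features. Includes a
    synthetic-data generator that emulates the factorial design with planted,
    fully registered effects so every stage is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
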