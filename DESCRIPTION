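Package: hostNiche
Title: Phylogenetic and Functional Niche Breadth of Parasites from Host
    Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the host specificity of parasites as the inverse of
    their phylogenetic and functional niche breadth. Computes tree-slicing
    phylogenetic diversity (lineage richness averaged over the evolutionary
    periods of an ultrametric host tree) and Rao's quadratic entropy on Gower
    trait dissimilarities for each parasite's host assemblage at regional and
    continental scales; estimates within-species repeatability (intra-class
    correlation) of these metrics with parametric-bootstrap confidence
    intervals; and relates niche breadth to parasite abundance, body size and
    regional host-pool diversity through phylogenetic generalized least
    squares with Pagel's lambda, kappa and delta optimized by maximum
    likelihood. Includes tree preparation utilities (edge-aware consensus,
    ultrametrization, polytomy resolution, taxonomy-to-tree conversion) and a
    synthetic-data generator reproducing the statistical structure of
    region-structured host-parasite survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape (>= 5.0),
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    cluster,
    lme4,
    nlme,
    withr
Config/testthat/edition: 3
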