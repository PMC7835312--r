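Package: funbeta
Title: Taxonomic and Functional Beta Diversity Along Environmental Gradients
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying taxonomic and functional beta diversity of
    microbial communities sampled along environmental gradients. Implements
    abundance-based pairwise similarity indices (Bray-Curtis, Simpson,
    Sorensen with replacement/richness-difference partitioning), multiple-site
    Sorensen beta diversity partitioned into turnover and nestedness
    components, Gower-distance functional dendrograms with tree-based
    functional beta diversity, generalized dissimilarity modelling (monotone
    I-spline transforms, negative-exponential link, non-negative least-squares
    fitting, permutation-based predictor importance), distance-decay
    regressions with halving distances, and a species-loss resampling
    experiment that quantifies how the functional similarity of communities
    degrades as species are randomly removed. Includes a niche-based community
    simulator (Gaussian niches along a gradient, multinomial counting effort,
    tunable functional redundancy) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    ape,
    cluster,
    geosphere,
    jsonlite,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    readxl,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
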