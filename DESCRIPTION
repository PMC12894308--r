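Package: n2onet
Title: Microbial Co-Occurrence Networks and Drivers of Soil N2O Emission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links soil microbial community structure to potential
    denitrification-derived nitrous oxide (N2O) emission rates. From
    genus-level bacterial and fungal count tables the package filters
    low-abundance genera, computes trimmed-mean-of-M-values (TMM)
    normalization factors, infers signed co-occurrence networks by
    thresholded Spearman correlation, and summarises network topology,
    modules (Louvain), within-module degree z-score keystones, robustness
    under random node removal, and per-sample positive/negative cohesion.
    Ecological statistics (alpha diversity, Levins niche breadth, ANOSIM,
    one-way ANOVA with Fisher LSD letters, incubation-series N2O rates)
    and a random-forest driver analysis on PCA composite indices rank the
    determinants of N2O emission. A seeded synthetic community generator
    with planted correlation modules and known N2O effects makes the full
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    edgeR,
    vegan,
    ape,
    picante,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
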