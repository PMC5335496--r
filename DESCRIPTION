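Package: micronorm
Title: Normalization and Differential Abundance Benchmarking for Microbiome Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how normalization and two-group differential
    abundance testing behave on sparse microbiome count tables. Implements the
    common normalization strategies (rarefying, total-sum scaling, log upper
    quartile, cumulative sum scaling, median-of-ratios size factors with a
    variance-stabilizing transform, trimmed mean of M-values), two-group tests
    ranging from rank tests to negative-binomial GLMs, a voom-style weighted
    moderated t, a zero-inflated Gaussian mixture, and the compositional ANCOM
    W procedure; multinomial, Dirichlet-multinomial and gamma-Poisson community
    simulators with recorded ground truth; distance/ordination/PAM-clustering
    and sequential-sums-of-squares PERMANOVA evaluation machinery; and grid
    runners that summarize sensitivity and false discovery rate across designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape,
    vegan,
    cluster,
    biomformat,
    phyloseq
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    limma,
    edgeR,
    DESeq2
Config/testthat/edition: 3
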