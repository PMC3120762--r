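Package: demeflow
Title: Phylogeographic Model Selection and Coalescent Dating for Multi-Deme Haplotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for statistical phylogeography of intraspecific haplotype
    data sampled from a small number of geographic demes. The package
    simulates alignments under the structured coalescent with constrained
    migration and recent demographic expansion, collapses alignments to
    haplotype tables with diversity and segregating-site statistics, builds
    statistical-parsimony haplotype networks, ranks explicit colonization
    scenarios encoded as constrained migration-rate matrices by maximum
    likelihood and AIC, and dates demographic expansions with a Bayesian
    coalescent skyline model under a strict molecular clock, including
    Bayes-factor comparison against a constant-size model via
    stepping-stone sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
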