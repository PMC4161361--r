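Package: qtlasso
Title: Multiple-QTL Mapping for Discrete Traits by Iteratively Reweighted LASSO
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous mapping of multiple quantitative trait loci (QTL) for
    binary, binomial, Poisson and normal traits in experimental crosses
    (backcross, doubled haploid, recombinant inbred lines, F2).  Genotype
    indicators at putative loci between markers are replaced by their
    conditional expectations given flanking markers (Haley-Knott regression),
    and the resulting heterogeneous over-dispersion is absorbed by
    standardizing the linear predictor per individual.  Genetic effects are
    estimated by an iteratively reweighted L1-penalized generalized linear
    model solved by coordinate descent, followed by an unpenalized refit of
    the selected loci for effect estimation and t-based significance testing
    against genome-wide thresholds obtained from null-model simulation or
    phenotype permutation.  Includes a cross/phenotype simulator for power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
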