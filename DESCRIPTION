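Package: plastcomp
Title: Comparative Structure and Sequence Evolution of Plastomes Lacking
    an Inverted Repeat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing plastid genomes that have lost one copy of
    the large inverted repeat (IR) against close relatives that retain the
    canonical quadripartite structure. Provides annotated-plastome
    input/output with quadripartite partitioning and IR collapsing,
    signed-permutation construction with exact minimum-inversion (reversal)
    distances, sorting scenarios and a breadth-first-search oracle, exact
    dispersed-repeat and microsatellite detection with redundancy filtering
    and repeat/inversion endpoint association, base-composition and
    codon-usage statistics, indel and single-nucleotide-variant frequencies,
    MG94-style codon-model estimation of synonymous and nonsynonymous rates
    with branch-model likelihood-ratio tests, and phylogenetically corrected
    group comparisons (generalized-least-squares t-test, phylogenetic
    regression, and simulation-based phylogenetic ANOVA with post-hoc
    tests). A synthetic-data module generates quadripartite plastomes,
    inversion histories, codon alignments and Brownian traits with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    MASS
Config/testthat/edition: 3
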