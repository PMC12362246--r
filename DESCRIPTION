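Package: relaxscan
Title: Branch-Partitioned Codon Models of Drift and Selection in
    Vertically Inherited Symbiont Genomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for asking whether molecular
    evolution in a clade of vertically inherited bacterial symbionts is
    dominated by genetic drift or by natural selection, relative to
    free-living relatives.  Implements an MG94xHKY codon substitution
    model with a mixture of dN/dS (omega) categories and a branch-level
    relaxation coefficient k (test branches evolve under omega^k), a
    likelihood-ratio test classifying orthogroups as drift-affected,
    selection-dominated or not significant, genome-wide per-branch dN/dS
    estimation with low-dS masking, Dollo parsimony mapping of gene-loss
    events, pseudogene-aware core/pan-genome accounting, empirical-null
    binomial pathway enrichment with Benjamini-Hochberg correction, and a
    synthetic-data generator that emulates the derived tables and codon
    alignments of a symbiont/free-living genome panel so the entire
    pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
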