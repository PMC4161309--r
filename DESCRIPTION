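Package: sagevo
Title: Strain Divergence and Recombination from Single-Amplified Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of closely related bacterial strains
    recovered as single-amplified genomes (SAGs): removal of
    index-misassigned reads using ultra-high-coverage regions, contig
    quality filtering and completeness estimation against a minimal
    essential gene set, ortholog clustering by Markov clustering of a
    protein similarity graph, synonymous and nonsynonymous divergence
    estimation (Nei-Gojobori counting and a pairwise maximum-likelihood
    codon model), ternary relative-dS analysis, recombination detection
    (Hudson-Kaplan minimum event counts, gene-conversion fragment
    scanning with a permutation null, r/m ratios), distance-based
    phylogenies with bootstrap support and topology-concordance
    counting, and a strain/read simulator with ground-truth ledgers so
    every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
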