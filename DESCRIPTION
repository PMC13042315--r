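Package: bafscreen
Title: Intraspecies Contamination Screening from B-Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies within-species contamination in short-read
    genome resequencing data from the distribution of B-allele frequencies
    (BAF) at variant sites. Provides a synthetic-data generator for
    contaminated read mixtures over haploid to tetraploid genomes, band-model
    ploidy classification and contamination-fraction estimation with a 5
    percent genome-wide calling threshold, a simplified binomial
    genotype-likelihood consensus caller with phred Q40 masking and base-call
    composition accounting, distance-based phylogenetics (Tamura-Nei and F84
    distances, neighbor joining with bootstrap, Robinson-Foulds placement
    diagnostics, exact one-dimensional k-means panel selection), and exact
    r-by-2 contingency tests for comparing contamination rates among studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    ggplot2,
    Rcpp,
    stats,
    utils,
    yaml,
    vcfR,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
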