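Package: paleodup
Title: Whole-Genome Duplication Detection from Paralog Divergence Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics toolkit for detecting and dating
    whole-genome duplication (WGD) events from gene-pair divergence
    distributions. Implements reciprocal-best-hit (RBH) ortholog and paralog
    calling over Smith-Waterman protein alignments, codon-aware
    back-translation, Nei-Gojobori (NG86) synonymous substitution rates with
    Jukes-Cantor correction, transversion rates at fourfold-degenerate sites
    (4dTv), Gaussian-mixture peak detection with BIC model selection and
    molecular-clock dating, collinearity block chaining by dynamic
    programming, tandem-duplicate classification, synteny depth profiling,
    orthologous-gene-cluster (OGC) classification by species composition, and
    cluster-level binomial functional enrichment with Benjamini-Hochberg
    adjustment. Ships a genome-evolution simulator (K80 substitution with
    stop-codon rejection, WGD, tandem duplication, rearrangements, and
    planted functional enrichment) that provides ground truth for every
    stage, plus a pipeline driver with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    mclust,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
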