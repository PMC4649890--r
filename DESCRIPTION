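Package: otukit
Title: De Novo OTU Clustering and Amplicon Read Preprocessing with a
    Ground-Truth Simulator
Version: 0.1.0
Authors@R:
    person("otukit", "developers", email = "otukit@example.org",
           role = c("aut", "cre"))
Description: Tools for processing marker-gene (16S rRNA, ITS) amplicon
    sequencing data: sliding-window quality trimming and primer removal,
    dereplication (exact-prefix and 100 percent identity modes), greedy
    abundance-seeded de novo OTU clustering with k-mer candidate ranking
    and a reject-counter early stop, gap-ignoring Needleman-Wunsch
    pairwise identity, a simplified two-parent (bimera) chimera detector,
    OTU tables with rarefaction and alpha-diversity estimators (Shannon,
    Simpson, inverse Simpson, Chao1), a 454-like amplicon community
    simulator with per-read ground truth, and truth-based evaluation
    metrics (redundant and chimeric OTUs, top-20 abundance residual sum
    of squares, OTU recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
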