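Package: simileR
Title: Significant Pairwise Alignment of Tandem Mass Spectra via Laplacian
    Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aligns pairs of fragmentation (MS/MS) spectra using the SIMILE
    approach: a pair-specific fragment-ion similarity matrix is derived from
    the frequencies of all pairwise m/z differences via a Markov chain, the
    directed graph Laplacian, and its Moore-Penrose pseudoinverse (a Euclidean
    commute-time embedding); fragment lists are then aligned by zero-gap
    Needleman-Wunsch dynamic programming, and the significance of the
    alignment score is estimated by an order-restricted Monte Carlo
    permutation test with early stopping. Includes MGF/MSP readers and an MGF
    writer, all-vs-all pair scoring, hit filtering, molecular-network
    construction with topology constraints, a maximum-common-substructure
    Jaccard rubric, and a synthetic block-molecule spectrum generator for
    ground-truth testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
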