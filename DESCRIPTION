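Package: alnvalid
Title: Clustering-Free Benchmarking of Protein Sequence Alignment Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks protein sequence alignment methods by how well the
    distances they induce separate known protein families, without running any
    clustering algorithm. Computes percent-identity distances from global
    Needleman-Wunsch pairwise alignments (implemented in compiled code with
    linear or affine gap penalties) and from pairwise projections of multiple
    sequence alignments, scores each distance matrix against family labels with
    the silhouette-width and R-squared (RS) cluster-validity indices, and runs a
    resampling protocol (90 percent subsamples, repeated) with Welch t-tests to
    compare methods. Includes a multi-family protein sequence simulator with
    controllable within- and between-family divergence and indels, external
    multiple-aligner adapters, and tidy tabular outputs with ggplot2 helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
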