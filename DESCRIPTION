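Package: ekgraph
Title: Evolutionary Kuramoto Games on Weighted Directed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the coevolution of communication strategies and
    oscillator phases on weighted, directed networks. Players carry a
    communicative label and a discrete Kuramoto phase; payoffs depend
    sinusoidally on phase mismatch and may be asymmetric between the
    communicator and the non-communicator. The package implements the
    birth-death Moran process with exponential fitness on an
    interaction/reproduction graph pair, ordinal 2x2 game-type classification,
    synchronization, chimera-like and metastability indices over
    constant-Potts-model communities, a rare-mutation analytic prediction of
    the well-mixed communicative fraction, and generators for connectome-like
    synthetic networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
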