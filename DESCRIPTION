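Package: clonofate
Title: Stochastic Descriptors for the Fate of Naive T Cell Clonotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time birth-death Markov model of a naive T cell
    clonotype competing for homeostatic proliferation signals in the
    periphery. Computes stochastic descriptors of clonal fate: the
    distribution and percentiles of the maximum clonal size before
    extinction, restricted (defective) moments of the time and of the
    number of division events needed to reach that maximum, moments of
    the time to contraction to a smaller clonal size, and the time to
    accumulate a given number of division events via an augmented
    (size, divisions) absorbing chain. Includes an exact Gillespie
    simulator as an independent Monte Carlo cross-check, tidy tabular
    summaries over parameter grids, and ggplot2 visualisations.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
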