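Package: avalanchr
Title: Neuronal Avalanche Scaling Analysis with Temporal Coarse-Graining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and scaling analysis of neuronal avalanches in
    population spike-density rasters. Implements hard- and soft-threshold
    epoch extraction, the temporal coarse-graining ensemble that compensates
    for spatial subsampling, maximum-likelihood power-law exponents with
    automated cutoff handling, the double power-law (crossover) fit of mean
    avalanche size versus duration, avalanche shape collapse, ordinal-pattern
    statistical complexity, lag-1 autocorrelation diagnostics, and a suite of
    surrogate controls (circular shifts, random spike addition, cell removal,
    trial shuffling). Ships a balanced excitatory/inhibitory probabilistic
    integrate-and-fire network with an aggregated population engine that
    scales to a million neurons, used as ground truth for critical versus
    subcritical cascade dynamics under subsampled observation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
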