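Package: sweepsim
Title: Simulating Incomplete Selective Sweeps and Evaluating
    Linkage-Disequilibrium Tests for Positive Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of favored-allele trajectories
    under complex demography (subdivision, migration, bottlenecks, expansions)
    with importance sampling conditioned on the modern sample count, a
    discrete-generation structured coalescent with recombination conditioned
    on those trajectories, infinite-sites mutation with discovery-panel
    ascertainment bias, and implementations of the haplotype-based selection
    statistics EHH, iHH, iHS, LRH, FRC and ALnLH together with a power /
    false-positive-rate / false-discovery-rate analysis framework for
    candidate-gene tests and empirical genome scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
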