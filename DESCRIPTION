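Package: lampcall
Title: Concatemer-Aware Analysis of LAMP Amplicons from Nanopore Sequencing
Version: 0.1.0
Authors@R: person("lampcall", "maintainers", email = "lampcall@example.org",
    role = c("aut", "cre"))
Description: Decomposes loop-mediated isothermal amplification (LAMP)
    concatemers sequenced on nanopore devices into target-bearing sub-reads,
    calls a hotspot allele per read by pileup plurality consensus, classifies
    every read (Target, Fragment, Spurious, Background, ONT, Short, Unknown),
    accumulates variant allele fraction with proportion confidence intervals
    and time-to-support diagnostics, predicts sequencing time from flow-cell
    parameters, and simulates labelled LAMP sequencing libraries so the whole
    pipeline is testable without real data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
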