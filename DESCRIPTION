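Package: strainfate
Title: Predicting Strain Fate in Long-Term Yeast Community Propagations
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative workflow of serial-transfer
    propagation experiments with fission yeast strain communities:
    a haploid multigenotype replicator model that forecasts a focal
    strain's frequency from pairwise per-generation selection
    coefficients, a Wright-Fisher-style bottleneck simulator for the
    1:500 serial-dilution regime, estimation of competitive fitness
    (S/g = ln(Rf/Ri)/t) from paired fluorescent/non-fluorescent flow
    cytometry counts, sliding-window log-linear estimation of maximum
    growth rates from microplate OD600 time series, a naive
    pileup-based variant filter with strand-bias rules and partitioned
    SNP/kb distance matrices, and synthetic-data generators with known
    ground truth for all of the above. A single command-line entry
    point exposes the pipeline stages as subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
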