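Package: cpsim
Title: Cross Potential Selection and Two-Part Breeding Program Simulation
Version: 0.1.0
Authors@R:
    person("cpsim", "developers", email = "cpsim@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of a two-part recurrent genomic selection
    breeding program for inbred crops, with three mate-selection strategies:
    truncation genomic selection (GS), optimal cross selection (OCS) under a
    scheduled genetic-diversity floor, and cross potential selection (CPS),
    which chooses crossing pairs by the usefulness criterion of future inbred
    (Inbred8) progeny solved exactly as an integer program. Includes phased
    genotype containers, Haldane-map meiosis and single-seed-descent selfing,
    a synthetic founder-panel generator, G-BLUP (EMMA-style REML) with
    marker-effect back-solving, and an exact closed-form engine for the mean
    and variance of inbred progeny derived from crosses between heterozygous
    parents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
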