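Package: retroscape
Title: Transposable Element Age Distributions, DNA Loss Rates, and
    Repeat Landscapes from Low-Coverage Shotgun Data
Version: 0.1.0
Authors@R:
    person("retroscape", "developers", email = "retroscape@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of repeat-masked low-coverage genomic
    shotgun data: corrected divergence (age) distributions of transposable
    element copies from their family consensus with exclusion of
    substitutions inherited from active master-element lineages, DNA loss
    rate estimation from small insertions and deletions in decaying
    non-LTR retrotransposon copies, and repeat-landscape summarisation in
    percent-of-genome and gigabase units. Includes a master-gene
    transposable element family simulator with exact per-copy ground
    truth, so every estimator is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
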