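Package: capture3c
Title: Calling Locus-Specific Long-Range Chromatin Interactions from
    dCas9 CAPTURE-3C Data
Version: 0.1.0
Authors@R:
    person("C3S", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Processes dCas9/sgRNA capture 3C sequencing libraries from
    aligned reads to significant long-range chromatin interactions.
    Implements restriction-junction (DpnII/GATC) read rescue, mapping
    quality filtering, mate pairing and PCR de-duplication of paired-end
    tags (PETs), adaptive bait-region definition from the dCas9 binding
    signal, genome binning at bait resolution, distance-stratified
    negative-binomial background models for intra-chromosomal contacts
    and per-chromosome models for inter-chromosomal contacts, and
    Bayes-factor significance calling with WashU longrange output.
    Includes a synthetic-data generator that emulates the statistical
    structure of capture 3C libraries so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rsamtools,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
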