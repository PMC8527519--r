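Package: magicpop
Title: Design and Simulation of Multiparental Advanced Generation
    Inter-Cross (MAGIC) Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to construct multiparental (MAGIC) crossing designs --
    full, partial balanced, partial unbalanced and basic funnel designs with
    replicates, selfing and an optional additional crossing generation --
    expand them into explicit pedigrees, simulate founder-labelled
    recombinant inbred line (RIL) populations through the pedigree using a
    Haldane (no-interference) meiosis model, and score competing designs by
    recombinant-haplotype and founder-genome metrics before any real
    crossing is done.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
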