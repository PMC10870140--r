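Package: hstkit
Title: Haplotype Sharing Trees and Ancestral Haplotype Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of uni- and bidirectional haplotype sharing trees
    (HSTs) from phased biallelic genotype data, derivation of majority-based
    ancestral and core haplotypes around a focal locus, carrier-haplotype
    selection, switch-error flagging, mutation-age (MRCA) estimation with the
    gamma method, repeat-class sharing analysis, cohort-to-haplotype and
    cohort-to-HST comparisons, and a founder-haplotype cohort simulator with
    known truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    vcfR,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
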