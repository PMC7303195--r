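Package: spateqtl
Title: Spatial Regulatory eQTL Mapping from Hi-C Fragment Contacts
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates disease-associated variants with Hi-C derived
    restriction-fragment contacts and tissue-stratified eQTL associations to
    call spatially supported SNP-gene regulatory pairs. Provides in-silico
    restriction digestion, fragment-level contact indexing, spatial pair
    derivation, Benjamini-Hochberg FDR control with cis/trans classification,
    regulatory annotation (histone-mark overlap, position-weight-matrix allele
    scoring, linkage disequilibrium), tissue-by-gene interaction
    summarisation, hypergeometric gene-set enrichment, a synthetic data
    generator with planted ground truth, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
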