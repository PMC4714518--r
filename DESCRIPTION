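Package: nhgpipe
Title: Multigenerational Heat-Stress Analysis of Germline Nuclear RNAi Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multigenerational temperature-shift
    experiments in C. elegans comparing wild-type and germline nuclear RNAi
    mutant (hrde-1) animals. Implements negative-binomial exact differential
    expression testing with median-of-ratios normalization, the derived
    gene-set cascade (heat-induced, nuclear RNAi-repressed heat-inducible
    genes and their high-stringency subset), Monte Carlo genomic association
    with LTR retrotransposon annotations, chromosome arm/center enrichment,
    Pol II and H3K9me3 generation-delta and trend analysis, phase-based
    antisense small RNA analysis, and a seeded synthetic-data generator that
    emulates the 12-generation experimental design for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
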