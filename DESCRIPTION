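Package: tagdge
Title: Tag-Based Digital Gene Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for restriction-anchored digital gene
    expression (DGE) tag profiling: extraction of clean 21-nt NlaIII
    (CATG) tags from raw reads, exact-match tag mapping against a
    reference transcriptome on both strands, tags-per-million (TPM)
    normalization, two-library exact differential-expression testing
    for count data with Benjamini-Hochberg false discovery rate
    control, fold-change summaries, hypergeometric term enrichment,
    and 2^-ddCt qPCR concordance checks. Includes a synthetic-data
    generator that emulates a two-species, two-treatment DGE study so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
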