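Package: maraprep
Title: Promoter-Level Pre-Processing of Expression and Chromatin Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces large RNA-seq, ChIP-seq and microarray datasets to small
    tab-delimited promoter-level (or probe-level) summary matrices suitable
    for upload to a motif activity response analysis (MARA) server, and
    manages local processing/submission jobs. Implements promoter-window
    read counting for ChIP-seq, exon-overlap read assignment with
    RPKM/TPM promoter expression for RNA-seq, and a microarray chain of
    normal+exponential background correction, non-specific-binding
    adjustment, expression filtering and quantile normalization. Includes
    deterministic synthetic-data generators for all three data types and a
    documented mock submission server for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    parallel,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    curl,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
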