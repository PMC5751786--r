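Package: lncord
Title: Cross-Species Identification and Functional Annotation of Conserved Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies high-confidence long non-coding RNAs (lncRNAs) from
    assembled transcript models by a filtering cascade (length, coding
    potential, expression, annotation-overlap class), pairs lncRNAs across
    two genomes by UCSC-chain coordinate liftover, and annotates conserved
    lncRNA families by three evidence streams: signed weighted co-expression
    network modules with hypergeometric GO enrichment and lncRNA-protein
    interaction support, bidirectional (divergent) lncRNA / protein-coding
    gene promoter pairs, and monotone temporal expression trends across
    developmental stages. Includes a deterministic two-genome synthetic-data
    generator with planted ground truth so the full pipeline is testable
    without external data, plus PhastCons-style conservation-score
    comparisons across gene classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
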