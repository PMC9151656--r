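Package: svtopo
Title: Structural Variant Topology and Complex Rearrangement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of structural variant (SV) junctions in cancer whole-genome
    data, with an emphasis on multiple myeloma. Builds per-sample junction
    graphs and classifies chained complex rearrangements as chromothripsis
    (clustered breakpoints with copy-number oscillation and loss of
    heterozygosity), chromoplexy (deletion bridges) or templated insertion
    (gain bridges); maps breakends to topologically associated domains (TADs),
    enumerates neo-TADs and nominates dysregulated genes by filtered ANOVA
    with Benjamini-Hochberg correction; bins translocation breakends into
    genomic hotspots; stratifies samples by SV burden with an elbow test; and
    compares complex events between paired timepoints. A seeded synthetic
    cohort generator with planted events and expression effects makes every
    stage testable without controlled-access patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
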