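Package: bandiv
Title: Diversity Analysis of Dominant Molecular Marker Band Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genetic diversity analysis of dominant molecular
    markers (SCoT/RAPD/ISSR amplicons, SDS-PAGE protein profiles, isozyme
    banding patterns) scored as binary presence/absence band matrices.
    Provides a validated band-matrix data model with delimited-text I/O,
    intensity-grade collapse and multi-assay pooling; per-locus polymorphism
    classification and genotype-specific (unique positive/negative) marker
    detection; per-primer informativeness indices (polymorphism information
    content, effective multiplex ratio, marker index, resolving power);
    Jaccard, Dice and simple-matching similarity matrices; UPGMA clustering
    with Newick export, cophenetic distances and cluster extraction; a
    seedable synthetic band-matrix generator with planted structure; and a
    pipeline reproducing a published diversity analysis of ten Egyptian
    bottle gourd cultivars from its printed band data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
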