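Package: invtad
Title: Chromosomal Inversions, Gene Flow and 3D Genome Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking chromosomal inversions, gene flow and
    3D genome organisation in diverging fish populations. Partitions a genome
    into inverted and colinear regions from whole-genome-alignment structural
    variant calls, computes windowed Weir-Cockerham FST and dxy and the
    ABBA-BABA D statistic (with block-jackknife standard errors) over the two
    region classes, derives A/B compartments (Knight-Ruiz balancing, leading
    eigenvector of the Pearson correlation matrix oriented by GC content) and
    TAD boundary sets from binned Hi-C contact matrices, and tests whether
    inversion breakpoints fall closer to TAD and compartment boundaries than
    expected under random placement (analytic expectation plus permutation
    null). A synthetic-data generator with known ground truth emulates every
    input so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
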