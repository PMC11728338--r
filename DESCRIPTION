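Package: HiCdci
Title: TAD Calling, Differential Chromatin Interactions and Locus
    Proximity Statistics for Hi-C Contact Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of binned Hi-C contact matrices for condition-paired
    designs: reading and writing Hi-C Pro sparse-triplet matrices, ICE
    (iterative correction) balancing, topologically associating domain (TAD)
    calling by unsupervised clustering of decay-corrected contact profiles,
    per-bin differential chromatin interaction (DCI) scoring between paired
    conditions, replicate consensus of DCI regions and their matching to TAD
    boundaries, locus-to-region proximity statistics (Spearman rank
    association and a genome-randomization permutation test), and TAD
    size-distribution comparisons by the Mann-Whitney U test. Includes a
    synthetic Hi-C generator with planted TADs, planted differential windows
    and expressed retroviral loci so that every stage is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    data.table,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: HiC, Epigenetics, Software, StatisticalMethod
RoxygenNote: 7.3.3
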