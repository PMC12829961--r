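Package: waveTAD
Title: Resolution-Free Probabilistic Calling of TADs and Loops from Hi-C
    Contact Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls topologically associating domains (TADs) and loops from
    Hi-C contact pairs without fixing an analysis resolution a priori. Valid
    intrachromosomal contacts are split into 5' and 3' strand-oriented
    groups, reduced to per-base coverage signals, and decomposed with a
    maximum-overlap discrete wavelet transform (coiflet c6). Detail
    coefficients are tested against a conservative wavelet-variance null,
    Holm-adjusted, and merged into left/right boundary calls; boundaries are
    paired, validated with a HiCCUPS-style donut enrichment test at the
    predicted TAD apex or loop anchor across binned resolutions, refined
    with a TopDom-style diamond statistic, and scored with a per-structure
    strength (the product of boundary and anchor probabilities). Also
    provides boundary-concordance metrics (Jaccard index, overlap
    coefficient, TPR/FDR), a compartment polarization index from 3D imaging
    coordinates, a strength-frequency quantile correlation, and a synthetic
    Hi-C contact simulator with planted TAD/loop structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: HiC, Epigenetics, FunctionalGenomics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
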