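Package: neosex
Title: Mapping and Characterization of Young Sex Chromosomes from
    Pooled Sequencing and Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for localizing a sex-determining region
    (SDR) from pooled resequencing of phenotypic-sex pools (Hudson F_ST
    genome scans, sex-specific variant filtering, replicate intersection and
    minimal-interval SDR calling), for quantifying X/Y divergence
    (windowed nucleotide identity, Nei-Gojobori Ka/Ks with evolutionary-strata
    changepoint scanning, repeat-subfamily Z-score landscapes and
    satellite-based centromere localization), for reconstructing the fusion
    origin of a neo-sex chromosome from synteny anchors (collinear block
    chaining, rearrangement-breakpoint counting, fusion-site detection and
    highly-rearranged-region delimitation), for comparative Hi-C architecture
    (ICE balancing, observed/expected transforms, A/B compartments,
    insulation-score TAD calling, distance-stratified significant-interaction
    calling, inter-chromosome contact scores) and for distance-geometry 3D
    chromosome reconstruction with Procrustes comparison. A synthetic-data
    module generates every input class with planted ground truth so the whole
    pipeline is exercisable and testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
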