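Package: homologDA
Title: Differential Chromatin Accessibility Between Homologous Metaphase
    Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies locus-specific differences in chromatin accessibility
    (DA) between homologous metaphase chromosomes as reported by short
    single-copy FISH probes.  Probe hybridization boundaries are delineated
    with gradient-vector-flow (GVF) active contours and summarized as
    background-corrected integrated intensities and normalized homolog
    intensity ratios; per-cell categorical scores (bright, intermediate,
    dim, nil) are classified as DA, equivalent, or excluded, and tested for
    non-random homolog preference with a two-proportion z-test.  Additional
    stages measure probe volume and axial depth in reconstructed 3D optical
    sections, aggregate open-chromatin signal (DNase I HS, FAIRE, histone
    marks) over probe intervals, and compare DA against equivalently
    accessible regions.  A synthetic-data module generates images, voxel
    stacks, score tables, and signal tracks with known ground truth so every
    stage has parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
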