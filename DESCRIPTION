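Package: perilad
Title: Quantifying Chromatin Tethering at the Plant Nuclear Periphery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis toolkit for testing whether plant lamin-like proteins
    tether chromatin at the nuclear periphery (NP). Implements 3D nucleus
    segmentation and distance-to-periphery measurement for FISH signals,
    per-nucleus cumulative chromosome-painting profiles and the P0.5 perinuclear
    statistic, iterative (ICE) balancing of Hi-C contact matrices with A/B
    compartment calling and compartment-strength quantification, LASSO modelling
    of chromatin-NP interaction signal with a distance-to-pericentromere feature,
    and SICER-style window/gap island calling of broad ChIP enrichment with
    replicate intersection into plant lamina-associated domains (PLADs).
    A synthetic-data module generates nuclei, contact matrices and read-count
    tracks with the statistical structure each stage assumes, so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    tiff,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
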