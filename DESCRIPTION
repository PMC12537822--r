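Package: spotcode
Title: Color-Barcode Encoding and Decoding for Multi-Round Multiplexed FISH
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for combinatorial fluorescence barcoding in multi-round,
    multi-channel fluorescence in situ hybridization (FISH) experiments.
    Builds and validates F-color, N-round codebooks, screens oligonucleotide
    primary probes against melting-temperature and sequence-composition
    constraints, and models the assembly arithmetic of dendritic DNA
    nanostructure amplifiers. A bundled synthetic-image simulator generates
    multi-round spot fields and segmented tissue scenes with full ground
    truth, which feed the analysis pipeline: cross-correlation image
    registration, Laplacian-of-Gaussian spot detection with subpixel
    localization, per-spot and per-cell-mask barcode decoding, and
    quality-control statistics (colocalization rates, probe-stripping
    retention series, distance-to-nucleus measures, laminar kernel density
    depth profiles, and cell-type frequencies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
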