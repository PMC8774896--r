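Package: octlayers
Title: Graph-Based Segmentation of Retinal Layer Boundaries in OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Segments the nine retinal layer boundaries (ILM through RPE-choroid)
    in optical coherence tomography B-scans by minimum-cost path search on a
    gradient-weighted pixel graph. The photoreceptor inner/outer segment junction
    (IS-OS) is detected first on a contrast-enhanced image; the remaining eight
    frontiers are then found sequentially inside regions of interest anchored to
    previously detected boundaries, each with its own transition polarity
    (dark-to-bright or bright-to-dark) and exponential gradient weighting.
    Includes total-variation denoising, adaptive binarisation, a synthetic
    B-scan phantom generator with ground truth (speckle, drusen, fluid pockets),
    signed-error/absolute-error evaluation, stage re-runs with adjusted
    parameters, manual boundary overrides, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    igraph,
    png,
    tiff,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
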