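Package: gutopt
Title: Optical Projection Tomography Simulation, Virtual Unfolding and
    Quantification for Tubular Gut Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mesoscale optical projection tomography (OPT) of
    tubular intestinal samples: simulation of parallel-beam projection sets
    over a full 360 degree rotation and slice-wise filtered back-projection
    reconstruction; virtual unfolding of the gut wall (per-slice tissue
    segmentation, seam selection, outline-guided straightening and
    orthogonal reslicing); quantification of villous density by
    Laplacian-of-Gaussian local maxima, segmentation of isolated lymphoid
    follicles with per-object volume and spacing statistics, and immune
    cell density per nuclei-mask area; and reverse-OPT bookkeeping that
    maps regions of interest selected in a reconstruction onto physical
    cryosection indices. A synthetic two-channel gut phantom generator
    with exported ground truth makes every stage testable without
    acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
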