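Package: nanotrace
Title: Filament Tracing, Worm-Like-Chain Inference and Vesicle
    Morphometrics for RNA Origami Nanotubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis toolkit for genetically encoded RNA
    origami cytoskeletons and their expression in giant unilamellar
    vesicles (GUVs). Provides a ground-truth synthetic data generator
    (worm-like-chain filaments, AFM-like height images, two-channel
    confocal-like GUV scenes, and coarse-grained nanotube trajectories in
    the oxDNA text dialect), skeleton-based filament tracing with
    longest-path resolution of branches, persistence-length estimation by
    fitting the worm-like-chain end-to-end relation with residual
    masking, per-frame persistence and structural statistics (mean
    structure, RMSF, designed-bond occupancy, inter-duplex angles,
    kissing-loop quality filtering) for coarse-grained trajectories, and
    GUV morphometrics (circle detection, segmentation, area fractions,
    radial centre of mass, circularity, angular intensity sampling,
    Welch's t-test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
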