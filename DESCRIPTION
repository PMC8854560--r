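Package: spinenano
Title: Nanoscale Organization Analysis of Synaptic Protein Clusters in
    Dendritic Spines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of multi-channel 3D STED-style image
    stacks of dendritic spines: spine-head ROI masking from a cell-fill
    channel, nanocluster (nanomodule) detection by local thresholding and
    connected components, 3D local-maxima seeded segmentation, assignment
    of clusters to spines with synaptic/non-synaptic classification,
    center-to-center 3D distance analysis in physical coordinates, optical
    calibration operators (FWHM, bead peak-to-peak, chromatic offsets),
    and the statistical layer relating nanocluster number and position to
    spine size (Gaussian count-distribution fits with extra sum-of-squares
    F test, scaling regressions with ANCOVA, Kolmogorov-Smirnov and
    ANOVA/Tukey comparisons, multivariable size regression, and a
    chemical-LTP potentiation classifier). Includes a ground-truthed
    synthetic scene generator emulating the imaging geometry so the whole
    pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
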