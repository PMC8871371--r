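Package: omiflim
Title: Optical Metabolic Imaging Analysis for Fluorescence Lifetime Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of label-free optical metabolic imaging
    (OMI) experiments built on time-correlated single photon counting
    (TCSPC) fluorescence lifetime microscopy of NAD(P)H and FAD. Provides
    per-pixel two-component exponential decay fitting with instrument
    response function convolution, intensity-based macrophage segmentation
    with reporter-channel activation scoring, per-cell optical endpoints
    (optical redox ratio, mean lifetimes, lifetime component fractions and
    the OMI index), and cohort-level general linear models with
    cluster-robust standard errors for cells nested in larvae and
    experiment days. A synthetic TCSPC scene generator with Poisson photon
    statistics makes the whole pipeline testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    emmeans,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
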