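Package: retinodex
Title: Quantification of Retinal Mitochondrial Redox State, OCT Layer
    Thickness, and Electroretinogram Amplitudes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible quantification stack for studies of retinal
    degeneration and photobiomodulation. Implements the 3D cryo-fluorescence
    NADH/FAD redox-ratio pipeline (voxelwise ratio, retinal-shell
    segmentation, maximum intensity projection, mean redox ratio, and the
    between-group oxidative-shift statistic), longitudinal-reflectivity-profile
    analysis of SD-OCT B-scans (registration and averaging, reflectivity-based
    layer-boundary detection, total-retina and outer-nuclear-layer thickness),
    electroretinogram a-/b-wave and flicker amplitude extraction, and
    photoreceptor-row histomorphometry. A seeded phantom generator produces
    synthetic eyes, B-scans, ERG traces, and nuclei masks with known ground
    truth for end-to-end recovery testing.
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
    png,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
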