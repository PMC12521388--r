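Package: depotmap
Title: Spatially Resolved SAXS and Raman Mapping of Lipid Liquid
    Crystalline Depots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for spatially resolved structural mapping of
    injectable lipid liquid-crystalline depots (soybean
    phosphatidylcholine/glycerol dioleate mixtures hydrating in buffer).
    Provides Bragg-peak detection and reflection-ratio indexing of 1D
    small-angle X-ray scattering curves with Fd3m/Pm3n/H2/lamellar
    libraries, Porod-invariant based cubic-phase-fraction maps with radial
    profiling and layer segmentation, pseudo-Voigt band fitting of Raman
    spectra with composition and hydration estimation from band-height
    ratios, a generalized-Fick (chemical-potential driven) transport
    simulator for water uptake and two-lipid redistribution, and a
    synthetic-data generator with known ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
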