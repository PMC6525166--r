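Package: ramanmcr
Title: Constrained Multivariate Curve Resolution for Raman Line-Focus
    Dehydration Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving metastable solid-state forms from
    time-resolved hyperspectral Raman line-scan data. Provides a
    ground-truthed synthetic generator for isothermal dehydration
    experiments (pseudo-Voigt band synthesis, sequential first-order
    kinetics with spatial defect heterogeneity, Poisson-Gaussian detector
    noise), stable-form residual mapping, library-constrained MCR-ALS
    with non-negativity, closure, unimodality and known-spectrum equality
    constraints, per-pixel non-negative least-squares unmixing into
    chemical concentration maps and metastable-only area plots, and a
    reproducible simulate-resolve-map pipeline with CSV/JSON archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
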