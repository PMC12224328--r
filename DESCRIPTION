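Package: nanocascade
Title: Cascade Kinetics, Enhanced Diffusion, and Cell-Response Analytics
    for Glucose-Powered Nanozyme Particles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis toolkit for experiments on glucose-fueled
    nanozyme particles that couple glucose oxidation to hydrogen peroxide
    decomposition on a single catalyst. Implements the cascade rate-law model
    with Michaelis-Menten production and Hill-type decomposition, its ODE
    simulation and pseudo-order steady-state reduction (steady-state H2O2 =
    k1/k2), initial-rate estimation and saturation-kinetics fitting;
    drift-corrected time-averaged mean squared displacement analysis of
    particle tracks with first-second linear fits to effective diffusion
    coefficients; microfluidic co-flow intensity-profile shift quantification
    for diffusiophoresis; and cell-scale analytics (random-walk motility
    summaries, wound-healing gap closure, shape circularity, quantitative
    phase imaging dry mass, and exponential doubling-time fits). Ships seeded
    synthetic-data generators for every input so the full pipeline is testable
    without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
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
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
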