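Package: histogrowth
Title: Lineage Statistics, Growth Simulation and Tissue Mechanics of the
    Pupal Abdominal Epidermis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying the growth of Drosophila
    histoblast nests, the progenitor cell clusters that build the adult
    abdominal epidermis. Computes lineage-derived proliferation statistics
    from tracked-cell tables (cell-cycle times, per-capita division rates
    with top-hat smoothing, division-rate Fourier spectra, growth
    decomposition into division, cell-area and extrusion contributions,
    cell-cycle arrest probabilities with Hill fits); simulates stochastic
    histoblast population growth with correlated sister cycle times, a
    proliferation pause and time-dependent arrest; analyses laser-ablation
    experiments (ellipse fitting, Hencky strain, recoil velocity,
    relaxation time); and fits an elastic-disc-on-elastic-foundation
    continuum model with anisotropic active tension to post-ablation
    deformation fields. Synthetic-data generators emulate every input so
    the full pipeline runs without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
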