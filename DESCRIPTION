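Package: hmcscatter
Title: Hamiltonian Monte Carlo Parameter Estimation for X-Ray Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gradient-based Markov chain Monte Carlo (Hamiltonian Monte Carlo
    and the No-U-Turn sampler, with dual-averaging step-size adaptation and
    mass-matrix preconditioning) for fitting physical models to X-ray
    scattering data. Ships forward models for small-angle scattering from
    polydisperse spheres, specular reflectivity of smeared multilayers via the
    effective-density model and Parratt recursion, and exit-angle-resolved
    fluorescence holograms from a buried emitter in a thin-film waveguide.
    Includes chain diagnostics (autocorrelation, effective sample size,
    significance tables, credible bands), seeded synthetic-data generators,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    splines
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
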