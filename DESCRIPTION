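Package: stenoflow
Title: Hybrid Nanofluid Boundary-Layer Flow in a Stenosed Artery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates steady boundary-layer flow and heat transfer of a
    hybrid nanofluid (alumina and copper nanoparticles suspended in blood)
    through an axisymmetric cosine-shaped arterial stenosis. Provides
    Brinkman/Maxwell mixture laws for the effective thermophysical
    properties, the similarity-reduced momentum and energy ordinary
    differential equations with selectable boundary-condition closures, a
    fourth-order collocation two-point boundary-value solver with a shooting
    cross-check, and post-processing of skin friction, Nusselt number and
    dimensional wall fluxes, together with parameter-sweep, published-table
    reproduction and unstated-parameter identification utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
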