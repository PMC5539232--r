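Package: rbcdem
Title: Discrete-Element Red Blood Cell Membrane Mechanics with
    Lattice-Boltzmann Flow Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constitutive modeling of red blood cell (RBC) and platelet
    membranes on triangulated discrete-element meshes.  Implements two
    membrane material models (a four-force constitutive model with
    strain-limited responses, and the coarse-grained spectrin-link
    worm-like-chain model), biconcave template mesh generation, quasi-static
    membrane experiments (optical-tweezer stretching, hexagonal-patch moduli
    extraction), force-bias packing of ellipsoid cell proxies for dense
    randomized initial conditions, and a minimal D3Q19 lattice-Boltzmann
    solver with immersed-boundary coupling for single-cell shear and channel
    flow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
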