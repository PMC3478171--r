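Package: delaypop
Title: Bifurcation Analysis of a Two-Population Neural Mass Model with Two Delays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the dynamical analysis of a lumped two-population model
    of neocortical activity with delayed intra-population inhibition and
    delayed inter-population excitation. Provides the non-dimensionalized
    model equations with a shifted tanh activation function, location of the
    (necessarily symmetric) equilibria, transcendental linear stability
    analysis through the factorized characteristic equation, Hopf boundary
    curves and assembly of the stability region in the gain plane, the first
    Lyapunov coefficient and generalized Hopf point for Hopf bifurcations of
    the origin, delay differential equation simulation with attractor
    classification, and collocation-based continuation of periodic orbits
    with Floquet multipliers and detection of period-doubling, fold-of-cycle
    and torus bifurcations. The machinery reproduces the one- and
    two-parameter bifurcation structure of the model, including the
    multistable regime in which two steady states and two periodic solutions
    coexist.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
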