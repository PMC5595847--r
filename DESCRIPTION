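Package: mtring
Title: Recurrent Ring-Network Model of Visual Motion Integration and
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a recurrent neural field (ring) model of
    direction-tuned populations such as those of primate cortical area MT.
    The package builds a two-parameter family of difference-of-Gaussians
    connectivity kernels with global lateral inhibition, drives the ring
    with uni- or bi-directional Gaussian-bump motion inputs, integrates the
    rate dynamics deterministically or with additive noise, classifies
    converged tuning curves as vector-average, winner-take-all/side-biased
    or two-peaked (transparency) solutions, estimates attractor strength by
    Monte-Carlo sampling of random initial conditions over stimulus and
    connectivity grids, performs pseudo-arclength continuation with
    eigenvalue-based stability analysis of the steady-state branches, and
    simulates the slow-inhibition temporal dynamics that shift the network
    from integration to segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
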