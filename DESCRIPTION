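Package: epichrom
Title: Coupled 3D Chromatin and 1D Epigenetic Dynamics of Stretched Recolourable Polymers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a stretched, "recolourable" bead-spring chromatin fibre in
    which per-bead epigenetic marks (colours) evolve by Metropolis recolouring
    while the 3D conformation evolves by Langevin dynamics, with like-colour
    attractions mediating the reader-protein bridging feedback. Includes
    builders for open and knotted initial configurations (trefoil, figure-eight,
    pentafoil and composites), a compiled Brownian-dynamics engine with terminal
    stretching forces, and a full analysis suite: epigenetic magnetisation,
    radius of gyration, kymographs, epigenetic-domain and boundary detection
    with boundary-diffusion estimation, Alexander-invariant knot localization on
    open chains, and characterisation of epigenetic knotted solitons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
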