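Package: follisim
Title: Multiscale Simulation and Analysis of Chemokine Gradients in B-Cell Follicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how CXCL13-producing follicular reticular cell
    networks shape chemokine gradients and B-cell migration. Synthesizes
    three-dimensional reticular networks with measured small-world topology,
    simulates immobilized versus soluble chemokine fields with a discretized
    reaction-diffusion model, steps B-cell agents with CXCR5 receptor kinetics
    and biased persistent random-walk motility, emulates the simulator with
    per-output feed-forward neural surrogates trained on Latin hypercube
    designs, and optimizes gradient parameters with NSGA-II against migration
    objectives. Companion statistical analyses include small-world network
    topology metrics, Moran's I spatial autocorrelation correlograms with
    permutation testing, and single-molecule track diffusion estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    lhs,
    Matrix,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
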