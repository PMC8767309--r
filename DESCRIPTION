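Package: bondprop
Title: Bond-to-Bond Propensity Analysis for Allosteric Site Detection
Version: 0.1.0
Authors@R:
    person("bondprop", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Constructs energy-weighted atomistic graphs from protein
    structures in PDB format, propagates perturbations from orthosteric
    bonds through the edge-to-edge transfer matrix of the weighted graph
    Laplacian, scores every bond and residue by distance-conditioned
    quantile regression, and evaluates candidate allosteric sites with six
    statistical measures backed by surrogate-site structural bootstrap and
    resampling confidence intervals. Includes seeded generators for
    synthetic structures, random weighted graphs and planted
    distance-decay propensity data so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
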