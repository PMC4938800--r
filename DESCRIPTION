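Package: ensmech
Title: Conformational Ensemble Mechanics of Protein Switch Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates equilibrium conformer ensembles from a single protein
    structure by iterative satisfaction of geometric distance constraints
    (a reduced-representation distance-geometry engine), and analyses the
    resulting ensembles with essential-dynamics principal component
    analysis, structural-alphabet fragment encoding, normalized
    mutual-information correlation networks, vector-pair hinge mechanics
    (bending/rotation angle distributions, Gaussian model selection,
    torsional stiffness), deletion-mimic engineering, and residue
    coevolution analysis of paired alignments (mean-field direct coupling
    analysis and APC-corrected mutual information). Ships synthetic-fixture
    generators (segmented helical hinge polymers, Potts-sampled paired
    alignments) with known ground truth so every analysis stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
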