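Package: cartloco
Title: Spatiotemporal Modeling of Locally Administered CAR T-Cell Therapy
    in Solid Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates the interaction between a radially symmetric solid
    tumor and chimeric antigen receptor (CAR) T cells delivered locally,
    either by intratumoral injection or by intracavitary administration.
    Tumor cells follow logistic growth with density-thresholded
    ("go-or-grow") diffusion; effector CAR T cells diffuse, kill tumor
    cells through a ratio-dependent saturating lysis term, proliferate in
    response to lysis, die, and convert to an exhausted compartment.  The
    coupled PDE system is integrated on a uniform radial grid with a
    conservative Crank-Nicolson scheme.  The package provides scenario
    construction (tumors grown to a target detectable size, both injection
    geometries), trajectory summaries and RECIST/Choi response
    classification, outcome maps over dose and exhausted fraction,
    minimum-effective-dose search, one-at-a-time sensitivity sweeps,
    method-of-manufactured-solutions convergence checks, and calibration
    of model parameters to longitudinal tumor-burden and CAR T-cell count
    time series via staged least squares and iterative latin-hypercube
    refinement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
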