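Package: kineticIsing
Title: Mean-Field Methods for Asymmetric Kinetic Ising Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward and inverse analysis of discrete-time kinetic Ising
    models with asymmetric couplings. Implements a family of Plefka
    mean-field approximations (naive mean field, TAP, correlation-
    conditioned expansions, a Gaussian effective-field method, and a
    pairwise expansion that preserves one coupling per spin pair) for
    activation rates, equal-time and delayed covariances; mean-field
    accelerated Boltzmann learning for parameter inference; entropy
    production estimators; the stationary mean-field solution and critical
    point of the asymmetric Sherrington-Kirkpatrick ensemble; and an exact
    enumeration oracle for validation at small system size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
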