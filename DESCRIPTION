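Package: rifabutinpk
Title: Joint Population Pharmacokinetics of Rifabutin and
    25-O-Desacetyl Rifabutin in Children on Lopinavir/Ritonavir
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a joint parent-metabolite population
    pharmacokinetic model for rifabutin and its active metabolite
    25-O-desacetyl rifabutin in children, including the CYP3A4
    drug-drug interaction with lopinavir/ritonavir. Provides a
    closed-form linear five-compartment structural model with
    allometric scaling and covariate effects, lognormal
    between-subject and between-occasion variability, a combined
    residual-error model with cross-analyte correlation, censored
    (below-quantification) observation handling, a Laplace/FOCE-type
    nonlinear mixed-effects estimator, prediction-corrected visual
    predictive checks, geometric-mean-ratio exposure comparisons, a
    synthetic study-data generator, and Monte Carlo simulation
    machinery for harmonized weight-band dose optimization against
    adult exposure targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
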