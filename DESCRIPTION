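Package: prucapop
Title: Pediatric Population Pharmacokinetics of Prucalopride
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population pharmacokinetic modelling pipeline for oral
    prucalopride in children with functional constipation. Implements a
    two-compartment disposition model with two sequential first-order
    absorption processes (rate switch at a fixed post-dose cut-off time),
    allometric body-weight scaling with a sigmoidal renal-maturation
    function on clearance, virtual-cohort simulation of a rich single-dose
    design and a sparse multi-dose design with mid-study dose adjustment,
    record-exclusion data preparation, population estimation by first-order
    conditional estimation with interaction (FOCE-I) including empirical
    Bayes individual estimates and shrinkage, goodness-of-fit and visual
    predictive check diagnostics, and age-by-dose steady-state exposure
    simulation against an adult reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
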