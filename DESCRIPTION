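Package: chemoconn
Title: Weighted Functional Connectome and Cohort Analysis for a Mouse
    Chemobrain Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational chain behind a rodent
    chemotherapy-induced cognitive impairment ("chemobrain") study:
    construction of weighted functional connectomes from regional
    resting-state time series, weighted small-world graph metrics with
    degree-preserving rewiring null models, group inference with a
    network-density covariate, scoring of rodent cognitive tests
    (puzzle box escape times, novel object/place recognition
    discrimination index, Y-maze spontaneous alternation), and
    bioenergetic and morphometric assay endpoints (mitochondrial
    stress-test respiratory capacities, mitochondrial atypia, ellipsoid
    tumor volumes, differential-expression reversal sets). A synthetic
    cohort generator produces all pipeline inputs with configurable
    group effects under explicit seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
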