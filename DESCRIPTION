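Package: bmgrowth
Title: Growth Exponents and Clonal Dynamics of Brain Metastases
Version: 0.1.0
Authors@R:
    person("MetGrowth", "Developers", email = "bmgrowth@example.org",
           role = c("aut", "cre"))
Description: Estimation of the Von Bertalanffy growth exponent (beta) from
    sparse longitudinal tumor-volume measurements of brain metastases: a
    three-point implicit solver, a multi-point discretized log-linear fit for
    dense (mouse-style) series, and a group-level grid sweep minimizing
    cumulative relative error. Includes sensitivity analyses of the exponent
    computation (canonical growth curves with random triplets; per-lesion
    perturbation screens), a stochastic discrete mesoscopic simulator of two
    competing clonal populations on a 3D voxel lattice with treatment
    operators, a synthetic-cohort generator for parameter-recovery testing,
    and a command-line pipeline with nonparametric group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
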