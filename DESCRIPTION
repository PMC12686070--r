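Package: terlake
Title: Threshold Elemental Ratios in a Lake Ecosystem Process Model
Version: 0.1.0
Authors@R: person("Analysis", "Group", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A chemostat-like lake ecosystem model of algal biomass and
    dissolved nitrogen and phosphorus, with Liebig-minimum Monod nutrient
    limitation and depth-averaged light limitation through algal
    self-shading (a Droop flexible-quota variant is included). The package
    sweeps nutrient-supply gradients to produce gross primary production
    (GPP) response curves, and locates and classifies threshold elemental
    ratios (TERs) on any response curve by competing flat, linear,
    saturating, logistic and breakpoint (hinge) models under small-sample
    corrected information criteria. A synthetic-curve generator with known
    ground truth supports validation of the detection stage, and a small
    command-line pipeline ties model runs, detection and reporting
    together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
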