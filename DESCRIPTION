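Package: riverTe
Title: Thermal Exposure Risk Modelling for River Fish Life Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A semi-distributed daily hydrological and water-temperature
    simulation engine for regulated rivers, coupled to a life-stage thermal
    exposure risk index for white sturgeon (Acipenser transmontanus).
    Provides synthetic-data generators (gridded watershed with drainage
    tree, seasonal meteorological forcing, pseudo-GCM scenario ensembles,
    noisy gauge observations, critical-habitat masks), a three-reservoir
    conceptual runoff model with linear channel routing and an
    equilibrium-temperature thermal module, two-step calibration of the
    hydrological and thermal parameters by covariance matrix adaptation
    evolution strategy (CMA-ES), the interval-based thermal exposure
    classifier with per-life-stage tolerance thresholds, ensemble and
    decadal aggregation of exposure categories, threshold-exceedance
    summaries, a proportional dam-release temperature controller, and a
    configuration-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    mgcv,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
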