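Package: awbevo
Title: Eco-Evolutionary Microbe-Enzyme Soil Carbon Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating soil organic carbon decomposition with an
    explicit microbe-enzyme (AWB-type) four-pool model in which the fraction of
    microbial uptake allocated to exoenzyme production is not a fixed parameter
    but the evolutionarily stable strategy of a resident-mutant competition
    game. Provides Arrhenius temperature response scenarios, closed-form and
    numerical steady-state solvers with local stability analysis, adaptive
    dynamics machinery (invasion fitness, selection gradient, pairwise
    invasibility plots), a first-order Q10 reference model calibrated against
    the mechanistic model, synthetic gridded climate forcing with polar-amplified
    warming, and decadal steady-state projections of soil carbon stocks and
    heterotrophic respiration with and without trait optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
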