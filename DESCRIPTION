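Package: jcpattern
Title: Spatial Point-Pattern Analysis of Janzen-Connell Effects in Mapped Forest Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to weigh Janzen-Connell distance- and density-dependent
    mortality against habitat association, dispersal limitation and
    self-thinning in fully mapped forest census plots. Implements
    edge-corrected O-ring pair-correlation, K/L, nearest-neighbour and
    spherical-contact statistics, the K2-function, Monte-Carlo simulation
    envelopes and goodness-of-fit rank tests, the Berman covariate test
    under a pattern-reconstruction (improvement-only simulated annealing)
    null model, heterogeneous Poisson null models from Epanechnikov kernel
    intensity estimates, quadrat-level topographic covariates (elevation,
    slope, convexity), and a synthetic stem-table generator with
    ground-truthed habitat filtering, clustered dispersal and switchable
    distance- and density-dependent mortality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
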