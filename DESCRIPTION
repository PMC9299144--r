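Package: warblerSMPM
Title: Stochastic (St)age-Structured Population Model for a Facultatively
    Cooperative Breeder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to build, simulate and interrogate a stochastic,
    density-dependent, (st)age-structured matrix population model of a
    facultatively cooperative breeding bird such as the Seychelles warbler.
    The life cycle distinguishes territory-holding dominant females from
    subordinate helpers and non-helpers on a half-year age grid; seasonal
    demographic rates are logistic functions of age, standardised population
    size, helper presence and the subordinate-to-dominant ratio, with
    environmental stochasticity injected by kernel resampling of fitted
    per-season intercepts.  Vacant dominant positions are allocated among
    surviving subordinates by a frequency-dependent weighted lottery whose
    single contrast parameter can be estimated by maximum likelihood from
    individual transition records.  The package computes stationary (st)age
    distributions, cohort-based lifetime reproductive success, moments of
    lifetime reproductive success via Markov chains with rewards,
    age-specific reproductive values, random-design life table response
    experiments with tree-ensemble variance attribution, elasticities of the
    stochastic mean population size, and an individual-based counterpart of
    the projection model for posterior-predictive-style checks.  A
    synthetic-data generator supplies seasonal parameter kernels and
    individual transition records with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
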