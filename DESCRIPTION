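Package: growsurv
Title: Latent Growth Curve Models with Joint Discrete-Time Survival for
    Memory and Brain-Volume Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits univariate and bivariate linear latent growth curve models
    with individually-varying observation times, practice-effect factors for
    repeated cognitive testing, and full-information maximum likelihood for
    missing outcomes. Trajectory estimates can be adjusted for death-related
    attrition by jointly modeling a discrete-time survival process whose
    latent hazard is regressed on the growth intercept and slope. Includes
    multiple-group estimation over reserve strata, Wald tests for equality
    of parameters, preprocessing utilities for memory composites and
    sex-stratified brain-volume standardization, and a synthetic cohort
    generator with informative mortality for design and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    TMB,
    pracma,
    jsonlite,
    yaml,
    rlang,
    ggplot2
LinkingTo: TMB, RcppEigen
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
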