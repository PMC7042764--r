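Package: songbirdIPM
Title: Multi-Site Integrated Population Models for Songbird Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a multi-site integrated population model (IPM) that joins
    route-level count surveys (BBS-like), constant-effort mist-netting
    capture-recapture data with transients (MAPS-like), and age-ratio
    productivity data, sharing adult apparent survival and a reproductive
    index across model components. Population change is modelled through
    truncated-Gaussian approximations of binomial survival and Poisson
    recruitment processes, with annual climate covariates (winter
    climate-moisture-deficit anomaly, spring temperature anomaly, and mean
    migration tailwind) entering logit-linear vital-rate models. Includes
    construction of the climate covariates from point samples, Bayesian
    fitting by MCMC, derived abundance indices and trends, transient life
    table response experiment (LTRE) decompositions of variation and change
    in realized population growth, and a synthetic-data generator with
    discrete demography for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
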