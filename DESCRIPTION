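Package: stcarmap
Title: Bayesian Spatio-Temporal CAR Disease Mapping for Areal Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-area disease mapping of areal count data over
    repeated survey periods. Builds queen-contiguity neighbourhood structures
    from polygon geometries, tabulates individual records into zone-by-period
    counts with quartile zone covariates, computes internally standardized
    expected counts and crude relative risks, and fits a Bayesian
    spatio-temporal Poisson log-linear model with intrinsic CAR (structured)
    and exchangeable (unstructured) zone random effects and a linear time
    trend by Metropolis-within-Gibbs MCMC. Includes convergence diagnostics
    (Gelman-Rubin, autocorrelation, Monte Carlo error), DIC model comparison,
    smoothed relative-risk surfaces with credible intervals and exceedance
    probabilities, and a synthetic-data generator that emulates zone-level
    child-anemia survey data on a lattice of zones.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
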