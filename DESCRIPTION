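Package: dpgrowth
Title: Dirichlet Process Clustering and Forecasting of Longitudinal Prevalence Trends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian semi-parametric hierarchical modelling of unbalanced
    longitudinal prevalence panels. Country-level trajectories are modelled as a
    global polynomial trend plus country-specific polynomial random effects whose
    prior is a Dirichlet process, so that countries with similar trends share a
    random-effect vector and cluster together. A Gibbs sampler with Chinese
    restaurant process label updates and an Escobar-West update for the
    concentration parameter yields posterior co-clustering summaries, point
    partitions, hold-out validation errors and forecasts for future survey waves.
    Ships transcriptions of the HBSC weekly/daily adolescent alcohol-use
    prevalence tables (40 countries/regions, survey waves 1985/86 to 2017/18) and
    a synthetic-panel generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
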