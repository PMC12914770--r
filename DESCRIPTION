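Package: vebayes
Title: Small-Sample Bayesian and Frequentist Intervals for Vaccine Efficacy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Interval estimation for vaccine efficacy (VE = 1 - IRR) from
    two-arm trial summaries (cases and person-years of surveillance per arm).
    Implements a full-likelihood Bayesian interval built on a bivariate
    central-limit approximation to the joint distribution of the surveillance
    time and the case count under randomly censored exponential infection
    times, with a compiled slice-within-Gibbs sampler; alongside the
    asymptotic maximum-likelihood interval, conjugate conditional-Bayesian
    credible intervals, and the Clopper-Pearson exact interval. Includes the
    censoring-law moment functionals for arbitrary recruitment processes, an
    event-driven sample-size formula, a recruitment-aware trial simulator,
    and a coverage/width study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
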