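Package: rtconf
Title: Sequential Sampling Models of Decision Confidence and Response Time
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint likelihoods, simulators, maximum-likelihood fitting,
    prediction, and group-level Bayesian model selection for sequential
    sampling models of binary choice, response time, and discrete
    confidence ratings. Implements the dynaViTE family of drift-diffusion
    confidence models (dynaViTE, dynWEV, 2DSD, DDConf), independent and
    partially anti-correlated Wiener race models with balance-of-evidence
    or time-dependent confidence (IRM, IRMt, PCRM, PCRMt), and the
    multiple-threshold log-normal race model (MTLNR). Includes parameter
    and model recovery pipelines and a precision benchmark for the
    numerical density approximations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    parallel
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
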