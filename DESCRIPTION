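Package: vaccshare
Title: Factorial and Structural Analysis of Public Support for Global
    Vaccine Sharing
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse survey experiments on public support for
    international COVID-19 vaccine sharing. Provides a synthetic
    survey-panel generator with quota-style demographic marginals, the
    2x2x5 factorial vignette design with mean-centered interaction design
    matrices, individual fixed-effects regression with cluster-robust and
    HC2 standard errors, a structural public-goods contribution model
    (log-benefit with convex costs and peer benchmarking) estimated by
    multi-start maximum likelihood with Wald inference, average treatment
    effect estimation for a two-arm information-video experiment, and
    descriptive surfaces: support CDFs by scenario grouping, beneficiary
    prioritization shares, and fair-share benchmark arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
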