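Package: wcnorm
Title: Weighted Continuous Norming for Psychometric Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constructing norm scores from demographically
    non-representative normative samples by combining post-stratification
    weighting (raking, i.e. iterative proportional fitting against marginal
    population distributions) with semi-parametric continuous norming
    (weighted tie-averaged percentile ranks, inverse normal transformation
    to the IQ metric, and polynomial regression of raw score on person
    location and age).  Includes a complete simulation framework: a
    demographically structured population generator with a developmental
    latent-ability surface, a 1-PL (Rasch) item-response test simulator,
    rank-based benchmark norms computed from a reference population, and
    RMSE/MSD bias evaluation across person-location bins, so that the
    behaviour of weighted versus unweighted norming can be studied under
    controlled departures from representativeness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
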