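Package: ratdecide
Title: Rational Sequential Decision-Making in Groups with Differing
    Preferences
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Exact computation and Monte-Carlo simulation of sequential
    binary collective decisions made by rational Bayesian agents whose
    utility functions are correlated but not identical.  Agents observe a
    noisy private estimate of their own utility and the ordered choices
    of previous deciders, and choose by comparing the private estimate
    against a recursively computed critical threshold.  The package
    provides the recursive threshold computation (via truncated
    multivariate-normal likelihoods and Gauss-Hermite quadrature),
    observer-side sequence and conditional choice probabilities under an
    experimental noise level, the relative social weighting statistic,
    exact group outcome enumeration with consensus scores, populations
    with two cryptic preference subtypes, and a generative Monte-Carlo
    simulator that serves as a brute-force oracle for every exact
    quantity.
License: MIT + file LICENSE
Imports:
    mvtnorm,
    statmod,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
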