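Package: rattention
Title: Rational Inattention Models of Tonic Dopamine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements a rational-inattention account of tonic dopamine in
    which a Gaussian Bayesian observer buys likelihood precision by trading
    reward incentive against a mutual-information cost of attention. Provides
    closed-form Gaussian encoding/decoding with separate true and estimated
    precision, the optimal-precision solution and its piecewise-linear
    incentive curve, a logarithmic subjective-time clock whose gain is set by
    precision, and simulation experiments for exploration-exploitation,
    feedback-learning asymmetry, timing central tendency, clock speed,
    controllability, post-reward delay underestimation, and discriminating
    predictions. All experiments return tidy tibbles and have ggplot2
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
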