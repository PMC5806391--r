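Package: voitrial
Title: Value-of-Information Design of Randomised Trials in Small Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Bayesian decision-theoretic (value-of-information) design of a
    two-arm confirmatory randomised controlled trial when the treatable
    population is small and known. Under a normal-normal conjugate model for
    the treatment effect, the package evaluates a closed-form monetary
    expected utility for any (sample size, significance threshold) pair,
    derives the analytically optimal one-sided threshold for each sample
    size, and maximises expected utility jointly over both, including the
    no-trial boundary where approval rests on the prior alone. Includes the
    conventional power-calculation comparator, frequentist operating
    characteristics (type I/II error sweeps over population size and
    treatment cost, no-trial population thresholds), a Monte Carlo oracle
    validating the closed form, and a worked haemophilia A case study with
    binary-endpoint arm summaries mapped to the monetary scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
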