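Package: crashmixl
Title: Crash Injury Severity Modelling with Random-Parameters Multinomial
    Logit and Heterogeneity in Means and Variances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-class (severe, minor, no-injury) crash severity
    analysis built around a random-parameters (mixed) multinomial logit model
    whose random coefficients have heterogeneity in both their means and their
    variances.  Provides KABCO recoding and descriptive cross-tabulations,
    a synthetic crash-record generator with stored ground truth, deterministic
    Halton quasi-random draw machinery, simulated maximum likelihood
    estimation with analytic scores, average discrete-change marginal
    effects, McFadden pseudo-R-squared, normal sign-share summaries, and the
    likelihood-ratio transferability test for separate group models.  All
    user-facing functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
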