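Package: herdopt
Title: Simulation, Linear Modelling and Desirability Optimization of Dairy Herd Productivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying drivers of milk productivity in dairy herds:
    a moment-matched synthetic generator for cow-day records (truncated
    skew-normal, truncated-geometric and truncated-exponential factor
    marginals with a linear response structure), descriptive-statistics
    panels with the (n+1)p quartile convention, main-effects ordinary
    least squares with adjusted (Type-III) sums-of-squares ANOVA,
    standardized-effect Pareto summaries, confidence and prediction
    intervals at arbitrary design points, and bi-objective box-constrained
    optimization of predicted milk yield against dry-matter intake via
    Derringer-Suich composite desirability with a grid-search oracle.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    e1071,
    pracma,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
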