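Package: netreliab
Title: Test-Retest Reliability of Graph-Theoretical Brain Network Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds binary and weighted functional brain networks from
    region-of-interest (ROI) time series under alternative processing
    strategies (global signal regression on or off, two parcellation sizes),
    sweeps proportional edge densities, computes seven global and three nodal
    small-world metrics with degree-preserving null-model normalization, and
    quantifies their test-retest reliability with the single-measure
    absolute-agreement intraclass correlation ICC(A,1) and the within-subject
    coefficient of variation. Includes a synthetic multi-subject,
    multi-session time-series generator with known variance components so the
    whole pipeline can be validated against ground truth, plus the repeated
    measures comparison statistics (paired t-tests, one- and two-way repeated
    measures ANOVA with Greenhouse-Geisser correction, Bonferroni post hocs)
    used to contrast processing strategies.
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
    igraph,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
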