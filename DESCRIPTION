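Package: tfactivity
Title: Transcription Factor Regulatory Activity Inference from ChIP-Seq and Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates transcription-factor binding potentials derived from
    ChIP-seq coverage with case-control gene expression to score each factor's
    differential regulatory activity. Binding affinities are computed by
    weighting coverage around transcription start sites with a
    factor-characteristic average profile, transformed into probability-like
    regulatory potentials, and combined with per-gene t-scores through a
    weighted running-sum statistic. Significance comes from balanced phenotype
    permutations with an empirical pooled false discovery rate. A sample-wise
    activity variant substitutes each sample's relative expression profile for
    the t-scores and normalizes against gene-permutation nulls; activity
    profiles can then be screened for association with patient survival using
    Cox proportional-hazards models with data-driven confounder selection.
    Seeded simulators generate coverage, potentials, expression and survival
    fixtures for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    limma,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
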