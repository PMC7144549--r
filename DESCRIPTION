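Package: erpool
Title: Simulation and Analysis of Replicated Evolve-and-Resequence Pool-Seq
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-stage evolve-and-resequence (E&R) studies on
    pooled sequencing data: forward Wright-Fisher simulation of replicated
    experiments with additive selection, two-stage pool-sequencing noise and
    dilution designs; sync-format count table input/output with SNP-catalog
    filters and a multi-mapper concordance filter; per-replicate Fisher's
    exact tests and across-replicate Cochran-Mantel-Haenszel tests;
    coverage-covariate p-value weighting with a budget constraint; empirical
    false-discovery-rate estimation against matched neutral simulations;
    temporal effective-population-size and selection-coefficient estimation
    from allele-frequency time series; and planning/validation analytics for
    secondary (dilution) experiments.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    broom
Config/testthat/edition: 3
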