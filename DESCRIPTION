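Package: phenometab
Title: Integrated Metabolomics and High-Throughput Phenotyping for Drought
    Stress Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for integrated analysis of
    high-throughput plant phenotyping time series and GC-MS metabolite
    profiles from drought-stress experiments. Provides quality control for
    imaging-derived trait time series (local-regression confidence-band
    flagging and group-wise standard-deviation filters), broad-sense
    heritability from variance components, loss-of-trait statistics, a
    complete metabolite preprocessing chain (blank filtering, presence
    filtering, minimum-fraction imputation, relative-standard-deviation
    filtering, median normalization, log10 transform and Pareto scaling),
    differential metabolite accumulation with false-discovery-rate control,
    OPLS-DA with VIP feature scoring, rank-product genotype tolerance
    ranking, cross-validated PLSR rank-product biomarker discovery, and
    hypergeometric pathway over-representation analysis. A synthetic-data
    generator with a ground-truth ledger supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mixOmics,
    multcomp,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
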