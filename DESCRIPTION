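Package: engraftr
Title: Donor Engraftment Analysis for Fecal Microbiota Transplant Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies donor-OTU engraftment in recipients of fecal
    microbiota transplantation (FMT) from 16S rRNA OTU count tables, using
    presence/absence set logic over donor, pre-FMT and post-FMT samples.
    Provides the surrounding trial analysis: OTU-table filtering and
    taxonomic aggregation, Shannon alpha diversity with paired timepoint
    comparisons, a statistical battery (Kruskal-Wallis with Dunn's
    posttest, exact Mann-Whitney U, Fisher and Freeman-Halton exact tests,
    one-way ANOVA and t-tests reconstructed from summary statistics),
    clinical outcome scoring (IBS-SSS, IBS-QoL, global improvement,
    adequate relief) with responder classification, and a synthetic
    FMT-trial generator with known ground-truth engraftment for end-to-end
    validation.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
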