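Package: iraesignal
Title: Disproportionality Signal Detection and Mechanism Screening for
    Immune-Related Adverse Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of immune-related adverse
    events (irAEs) in spontaneous-report databases, modelled on the FDA
    Adverse Event Reporting System (FAERS) quarterly ASCII distribution.
    Reads and deduplicates quarterly report files, classifies checkpoint
    inhibitor and chemotherapy exposure arms, computes reporting odds ratio
    (ROR), proportional reporting ratio (PRR) and Bayesian information
    component (IC) statistics with a five-way conjunction signal rule,
    performs time-to-onset and logistic-regression subgroup analysis, and
    screens candidate molecular mechanisms by single-sample gene set
    enrichment (ssGSEA), Spearman correlation against event-level RORs,
    exhaustive bivariate linear models selected by likelihood-ratio tests,
    and preranked gene set enrichment. A seeded synthetic-data generator
    emits FAERS-style quarterly files and expression cohorts with known
    ground truth so every stage is testable without external downloads.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
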