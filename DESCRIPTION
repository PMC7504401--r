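Package: beconcord
Title: Cross-System Concordance of Barrett's Esophagus Expression Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the molecular profile of Barrett's esophagus
    (BE) across experimental systems. Implements two-group differential
    expression with an empirical-Bayes moderated t-statistic and
    Benjamini-Hochberg false discovery rate control, a multi-dataset
    gene-selection procedure defining a human BE marker panel of squamous- and
    columnar-epithelium keratins, mucins, trefoil factors and villin, relative
    quantification of qPCR data by the 2^-ddCt method with dual reference
    genes and Dunnett many-to-one group comparisons, direction-of-change
    calling, and direction-concordance scoring of in vitro (Het-1A, EPC2) and
    in vivo (rat reflux) model systems against the human biopsy panel,
    including Venn set partitioning. A seeded synthetic-data generator
    produces expression matrices and Ct tables with known ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    mvtnorm,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    multcomp,
    optparse
Config/testthat/edition: 3
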