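Package: durumwp
Title: Water Productivity Analysis for Multi-Environment Durum Wheat Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for dissecting the genetics of water
    productivity in durum wheat multi-environment trials. Takes plot-level
    phenotype records through design-adjusted genotype means (augmented and
    alpha-lattice designs), variance partitioning and heritability, AMMI
    decomposition of genotype-by-environment interaction with the AMMI wide
    adaptation index (AWAI), climate-driven mega-environment clustering,
    water-productivity slope classification, mixed-model genome-wide
    association with kinship and population structure, LD-based QTL assembly,
    haplotype effect testing, and KASP-style marker validation metrics. Ships
    a synthetic-data generator that emulates the statistical structure of
    Mediterranean durum trials so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    stats,
    utils,
    jsonlite,
    withr,
    generics,
    igraph,
    emmeans,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
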