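Package: ribotagr
Title: Analysis of RiboTag Immunoprecipitation Experiments in Mixed-Species Co-Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of RiboTag/TRAP translatome immunoprecipitation
    (IP) experiments performed in two-species (human/mouse) co-cultures, where
    uniquely mapped reads are attributable to one species via a hybrid reference.
    Computes per-chromosome and per-species read composition, the off-target
    depletion-efficiency statistic (the negative slope of the regression of the
    per-chromosome change in percent uniquely mapped reads, IP minus input, on
    the input percent), gene-level enrichment deltas, permutation gene-set
    enrichment over Ensembl biotypes and chromosomes, and absolute reporter
    quantification from digital-PCR partition counts. Includes a generative
    simulator of co-culture IP experiments with analytic expectations so every
    stage of the pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
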