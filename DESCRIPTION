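Package: irilqtl
Title: Quantitative-Genetic Analysis and Multiple-QTL Mapping for
    Intermated Recombinant Inbred Line Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for biparental intermated recombinant
    inbred line (IRIL) populations such as the maize IBM (B73 x Mo17)
    population: genetic-map and genotype quality control (segregation
    distortion filtering, flanking-marker imputation), per-regime
    adjusted entry means and broad-sense heritability from replicated
    phenotype trials, partial-correlation trait networks, and a
    composite-interval multiple-QTL mapping engine with randomized
    bin-based cofactor selection, Haley-Knott regression scans,
    permutation-based genome-wide LOD thresholds, Bayesian credible
    intervals expanded to flanking markers, simultaneous multi-QTL fits
    and candidate-gene interval reports.  A gene-drop simulator
    generates IRIL populations with known QTL architecture so every
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
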