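Package: rnasurf
Title: Structural Disruption Scores for Synonymous Variants from mRNA Folding Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores every possible single-nucleotide variant of an mRNA
    transcript for its predicted disruption of local secondary structure.
    Folds 101-nt wild-type and mutant windows with a thermodynamic
    nearest-neighbour backend, derives ten per-variant disruption metrics
    (stability deltas, structure edit distances, ensemble diversity
    changes), classifies coding effect and mutational context, relates the
    metrics to population allele-frequency constraint through binned
    weighted regressions with mediator variance decomposition, and
    summarises them into two Phred-scaled pathogenicity scores: a
    Structural Predictivity Index (SPI) from paired null/active logistic
    models, and a maximum-percentile summary score (SURF). Includes a
    synthetic-data generator so the full pipeline runs at desk scale
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: ViennaRNA (RNAfold, RNApdist on the PATH)
Config/testthat/edition: 3
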