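Package: rhythmics
Title: Circadian Rhythm Detection, Differential Analysis, and Regulatory
    Network Inference for Time-Course Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for diel time-course transcriptome and
    metabolome experiments with a genotype-by-treatment design, modelled on
    gibberellin-mediated rhythmic leaf growth in maize. Detects circadian
    genes with a dual criterion (cosine molecular-timetable screen on
    coefficient of variation and template correlation, plus a JTK_CYCLE
    style rank test with an exact tie-aware null), calls differentially
    expressed genes and differentially accumulated metabolites (OPLS-DA
    variable importance in projection), infers transcription-factor
    regulatory networks with the context likelihood of relatedness (CLR)
    algorithm, and integrates transcripts with metabolites into a
    tripartite network. Ships a seeded synthetic-data generator that plants
    known rhythms, restoration trajectories, and regulatory edges so every
    stage is testable without external data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
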