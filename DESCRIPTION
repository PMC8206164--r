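Package: follitime
Title: Temporal Transcriptome Analysis of Cultured Ovarian Follicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-condition time-course transcriptomes of
    ovarian-follicle co-culture. Provides temporal k-means clustering of
    consensus expression profiles with cluster-specific differential
    expression (empirical-Bayes moderated t-statistics), trajectory-quality
    gene filtering based on cubic-fit percent variance explained, adjacent-lag
    cohesion and an unreplicated two-factor ANOVA interaction statistic,
    3x3 self-organizing-map subsetting of condition-divergent genes, and
    cross-dataset developmental-transition concordance via correlated
    t-scores with a Fisher-transformation test. Includes a fully labelled
    synthetic-data generator with planted trajectory archetypes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
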