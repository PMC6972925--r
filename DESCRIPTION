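Package: cagetss
Title: Separating Transcription Start Sites from Noise in CAGE Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes aligned CAGE (Cap Analysis of Gene Expression) reads
    into strand-specific tag clusters, extracts structural DNA profiles and
    RNA polymerase II core-promoter motif affinities around each cluster
    representative, and scores every cluster with a layered machine-learning
    stack (per-feature probabilistic support vector machines combined by
    stochastic gradient boosting) to separate genuine transcription start
    sites from transcriptional noise.  Includes the training-set construction
    rules, annotation- and chromatin-state-based evaluation benchmarks, and a
    self-contained synthetic-data generator with planted promoters so the
    whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    e1071,
    xgboost,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
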