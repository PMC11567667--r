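Package: seqprime
Title: Design Generation and Analysis for Overlapping-Sequence Learning Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for statistical-learning experiments built around overlapping
    object triplets (ABC1/ABC2 sequences sharing an AB stem). Generates constrained
    pseudo-random trial orders for learning, recognition-priming, pre/post exposure,
    and explicit-integration phases, and validates them against the design's
    transition-probability structure. Simulates a full synthetic cohort (trial-level
    response times, recognition responses, ROI voxel time series, resting-state
    courses) with known subject-level effect sizes, and implements the complete
    analysis chain: recognition-priming scores and mixed-effects models,
    nonparametric sensitivity A, single-trial-class GLM pattern estimation,
    integration-model fits to pattern-similarity matrices with pre/post change
    scores and BOLD controls, nuisance-regressed band-passed resting-state coupling,
    and across-subject inference (correlation comparisons, partial correlations,
    semi-partial R-squared regression, Bonferroni bookkeeping).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    lmerTest,
    signal,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
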