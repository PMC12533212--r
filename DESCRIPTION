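Package: stereolang
Title: Language-Based Measurement of Social Stereotypes About AI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying social-stereotype content in natural
    language representations of artificial intelligence. Implements the
    Single-Category Word Embedding Association Test (SC-WEAT) with
    permutation inference and a pooled standardized-regression estimator,
    the Fill-Mask Association Test (FMAT) against an injectable masked
    language-model adapter, placement of social groups in a
    four-dimensional competence-warmth space with Euclidean-distance
    contrasts, a log-probability-ratio probe of generative language models
    scoring occupations against benefit versus replacement prompts
    (including one-sample effect sizes, a JZS Bayes factor and prestige
    correlation), internal random-effects meta-analysis, and seeded
    synthetic-data generators with known ground truth so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
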